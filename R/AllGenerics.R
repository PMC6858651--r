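#' Accessors for package classes
#'
#' @param x An object of the corresponding class.
#' @param ... Further arguments (unused).
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{psiValues}: the PSI matrix (events x samples).
#' @export
setGeneric("psiValues", function(x, ...) standardGeneric("psiValues"))

#' @rdname accessors
#' @export
setMethod("psiValues", "PsiExperiment", function(x, ...)
  assay(x, "psi"))

#' @rdname accessors
#' @return \code{eventInfo}: \code{DataFrame} of event identities
#'   (symbol, as_id, splice_type, exon_label).
#' @export
setGeneric("eventInfo", function(x, ...) standardGeneric("eventInfo"))

#' @rdname accessors
#' @export
setMethod("eventInfo", "PsiExperiment", function(x, ...) rowData(x))

#' @rdname accessors
#' @return \code{spliceType}: character vector of per-event category codes.
#' @export
setGeneric("spliceType", function(x, ...) standardGeneric("spliceType"))

#' @rdname accessors
#' @export
setMethod("spliceType", "PsiExperiment", function(x, ...)
  as.character(rowData(x)$splice_type))

#' @rdname accessors
#' @return \code{chosenK}: the selected number of clusters (\code{NA} when
#'   no structure was found).
#' @export
setGeneric("chosenK", function(x, ...) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setMethod("chosenK", "ConsensusResult", function(x, ...) x@chosenK)

#' @rdname accessors
#' @return \code{clusterLabels}: integer cluster labels named by sample.
#'   For a \code{ConsensusResult}, the optional second argument \code{k}
#'   re-cuts the stored consensus matrix at a different k.
#' @param k Optional cluster number at which to cut (defaults to
#'   \code{chosenK}).
#' @export
setGeneric("clusterLabels", function(x, k, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x, k, ...) {
  if (missing(k)) return(x@labels)
  k <- as.integer(k)
  if (!k %in% x@kRange)
    stop("k = ", k, " was not part of the evaluated range")
  assignClusters(x@consensus[[as.character(k)]], k)
})

#' @rdname accessors
#' @return \code{consensusMatrices}: named list of per-k consensus matrices.
#' @export
setGeneric("consensusMatrices", function(x, ...)
  standardGeneric("consensusMatrices"))

#' @rdname accessors
#' @export
setMethod("consensusMatrices", "ConsensusResult", function(x, ...) x@consensus)

#' @rdname accessors
#' @return \code{clusterStats}: per-k data.frame of PAC, mean null PAC,
#'   RCSI and empirical p.
#' @export
setGeneric("clusterStats", function(x, ...) standardGeneric("clusterStats"))

#' @rdname accessors
#' @export
setMethod("clusterStats", "ConsensusResult", function(x, ...) x@stats)

#' @rdname accessors
#' @return \code{signatureTable}: per-event signature-call table.
#' @export
setGeneric("signatureTable", function(x, ...) standardGeneric("signatureTable"))

#' @rdname accessors
#' @export
setMethod("signatureTable", "SignatureSet", function(x, ...) x@table)

#' @rdname accessors
#' @return \code{signatureEvents}: character vector of assigned signature
#'   event ids, optionally restricted to one subtype via \code{subtype=}.
#' @param subtype Optional subtype label to restrict to.
#' @export
setGeneric("signatureEvents", function(x, subtype, ...)
  standardGeneric("signatureEvents"))

#' @rdname accessors
#' @export
setMethod("signatureEvents", "SignatureSet", function(x, subtype, ...) {
  tab <- x@table[x@table$assigned, , drop = FALSE]
  if (!missing(subtype))
    tab <- tab[tab$subtype == subtype, , drop = FALSE]
  tab$event_id
})

#' @rdname accessors
#' @return \code{networkEdges} / \code{networkFactors}: the edge and
#'   factor-node tables of a \code{CorrelationNetwork}.
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("networkEdges", "CorrelationNetwork", function(x, ...) x@edges)

#' @rdname accessors
#' @export
setGeneric("networkFactors", function(x, ...) standardGeneric("networkFactors"))

#' @rdname accessors
#' @export
setMethod("networkFactors", "CorrelationNetwork", function(x, ...) x@factors)
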