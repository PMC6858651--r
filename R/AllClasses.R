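#' @importFrom methods new validObject is as setClass setGeneric setMethod
#'   setValidity show slot
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' The seven splice-event categories
#'
#' Category codes used throughout the package: exon skip (ES), retained
#' intron (RI), alternate promoter (AP), alternate terminator (AT),
#' alternate donor site (AD), alternate acceptor site (AA) and mutually
#' exclusive exons (ME).
#'
#' @return Character vector of the 7 legal splice-type codes, in canonical
#'   order.
#' @examples
#' spliceCategories()
#' @export
spliceCategories <- function() {
  c("ES", "RI", "AP", "AT", "AD", "AA", "ME")
}

#' PsiExperiment: an events-by-samples PSI container
#'
#' A \linkS4class{SummarizedExperiment} holding one assay named \code{"psi"}
#' with percent-spliced-in values as fractions in [0, 1] (\code{NA} marks
#' missing measurements).  Row metadata identifies each splicing event by
#' gene \code{symbol}, integer \code{as_id}, \code{splice_type} (one of the
#' 7 category codes) and a free-text \code{exon_label}.  Row names are the
#' canonical event-id strings \code{"SYMBOL|as_id|TYPE|exon_label"}.
#'
#' @seealso [PsiExperiment()] for construction, [readPsiTable()] for import.
#' @aliases PsiExperiment-class
#' @exportClass PsiExperiment
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
  msg <- character()
  if (!"psi" %in% assayNames(object))
    msg <- c(msg, "assay 'psi' is required")
  else {
    v <- assay(object, "psi")
    if (!is.numeric(v))
      msg <- c(msg, "'psi' assay must be numeric")
    else if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "PSI values must lie in [0, 1] (or be NA)")
  }
  rd <- rowData(object)
  need <- c("symbol", "as_id", "splice_type", "exon_label")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    bad <- setdiff(unique(rd$splice_type), spliceCategories())
    if (length(bad))
      msg <- c(msg, paste0("unknown splice_type: ",
                           paste(bad, collapse = ", ")))
    key <- paste(rd$symbol, rd$as_id, rd$splice_type)
    if (anyDuplicated(key))
      msg <- c(msg, "(symbol, as_id, splice_type) must be unique")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PsiExperiment
#'
#' @param psi Numeric matrix of PSI fractions (events x samples), values in
#'   [0, 1] or \code{NA}.  Column names are sample ids.
#' @param events A \code{data.frame} or \code{DataFrame} with one row per
#'   event and columns \code{symbol}, \code{as_id}, \code{splice_type},
#'   \code{exon_label}.  May be omitted when \code{rownames(psi)} are
#'   parseable event-id strings (see [parseEventId()]).
#' @return A \linkS4class{PsiExperiment}.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("GENE1|1|ES|exon2", "GENE2|2|AT|exon5"),
#'                             c("s1", "s2")))
#' PsiExperiment(m)
#' @export
PsiExperiment <- function(psi, events = NULL) {
  psi <- as.matrix(psi)
  if (is.null(events)) {
    if (is.null(rownames(psi)))
      stop("'events' must be supplied when 'psi' has no row names")
    events <- do.call(rbind, lapply(rownames(psi), function(id)
      as.data.frame(parseEventId(id), stringsAsFactors = FALSE)))
  }
  events <- as.data.frame(events)
  rownames(psi) <- eventId(events)
  se <- SummarizedExperiment(assays = list(psi = psi),
                             rowData = DataFrame(events, row.names = rownames(psi)))
  new("PsiExperiment", se)
}

#' @describeIn PsiExperiment Number of events and samples.
#' @param object A \code{PsiExperiment}.
#' @export
setMethod("show", "PsiExperiment", function(object) {
  cat("PsiExperiment:", nrow(object), "splicing events x",
      ncol(object), "samples\n")
  tab <- table(factor(rowData(object)$splice_type, levels = spliceCategories()))
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  nmiss <- sum(is.na(assay(object, "psi")))
  cat("  missing PSI cells:", nmiss, "\n")
})

#' Consensus-clustering result
#'
#' Holds, for every candidate number of clusters k, the consensus matrix and
#' its stability statistics (CDF of consensus entries, PAC, mean PAC of the
#' simulated null references, RCSI and the empirical p-value), together with
#' the selected k and the final sample labels.
#'
#' @slot kRange Integer vector of candidate k.
#' @slot consensus Named list of samples-x-samples consensus matrices, one
#'   per k (entries in [0, 1], symmetric, unit diagonal).
#' @slot stats \code{data.frame} with one row per k: \code{k}, \code{pac},
#'   \code{meanNullPac}, \code{rcsi}, \code{empiricalP}.
#' @slot nullPac Named list of per-k numeric vectors of null PAC scores.
#' @slot chosenK Integer; \code{NA} when no k reached significance
#'   ("no structure").
#' @slot labels Integer vector of cluster labels at \code{chosenK} (named by
#'   sample), empty when no structure was found.
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
         representation(kRange = "integer", consensus = "list",
                        stats = "data.frame", nullPac = "list",
                        chosenK = "integer", labels = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (k in names(object@consensus)) {
    M <- object@consensus[[k]]
    if (!isSymmetric(unname(M), tol = 1e-8))
      msg <- c(msg, paste0("consensus matrix for k=", k, " not symmetric"))
    if (any(abs(diag(M) - 1) > 1e-8))
      msg <- c(msg, paste0("consensus diagonal for k=", k, " not 1"))
    if (any(M < -1e-8 | M > 1 + 1e-8))
      msg <- c(msg, paste0("consensus entries for k=", k, " outside [0,1]"))
  }
  if (nrow(object@stats) &&
      any(object@stats$pac < 0 | object@stats$pac > 1, na.rm = TRUE))
    msg <- c(msg, "PAC must lie in [0, 1]")
  if (length(object@labels) && !is.na(object@chosenK) &&
      length(unique(object@labels)) != object@chosenK)
    msg <- c(msg, "labels must take exactly chosenK distinct values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =", paste(range(object@kRange), collapse = ".."), "\n")
  print(format(object@stats, digits = 3), row.names = FALSE)
  if (is.na(object@chosenK))
    cat("  verdict: no structure (no k with empirical p < 0.05)\n")
  else
    cat("  chosen k:", object@chosenK, "(",
        paste(table(object@labels), collapse = "/"), "samples )\n")
})

#' Subtype signature-call result
#'
#' @slot table \code{data.frame}, one row per event: \code{event_id},
#'   \code{subtype} (assigned subtype or \code{NA}), \code{foldVsBest}
#'   (ratio of the top subtype mean to the best other subtype mean),
#'   \code{maxQ} (largest BH-adjusted Mann-Whitney q over the pairwise
#'   comparisons), \code{assigned} (logical).
#' @slot subtypeMeans Events-x-subtypes matrix of mean PSI.
#' @slot fold,fdr The thresholds used.
#' @aliases SignatureSet-class
#' @exportClass SignatureSet
setClass("SignatureSet",
         representation(table = "data.frame", subtypeMeans = "matrix",
                        fold = "numeric", fdr = "numeric"))

setValidity("SignatureSet", function(object) {
  tab <- object@table
  if (nrow(tab) && any(duplicated(tab$event_id)))
    return("each event may appear once")
  TRUE
})

setMethod("show", "SignatureSet", function(object) {
  tab <- object@table
  cat("SignatureSet:", sum(tab$assigned), "signature events of",
      nrow(tab), "tested (fold >=", object@fold, ", FDR <", object@fdr, ")\n")
  if (sum(tab$assigned)) {
    counts <- table(tab$subtype[tab$assigned])
    cat("  per subtype:", paste(names(counts), counts, sep = ":",
                                collapse = " "), "\n")
  }
})

#' Splicing-factor / splicing-event correlation network
#'
#' A bipartite signed network: splicing-factor nodes carry a prognostic
#' direction (favorable/unfavorable), event nodes are splicing events, and
#' edges are Spearman correlations passing \code{|rho| > rhoThreshold} and
#' \code{p < pMax}.
#'
#' @slot factors \code{data.frame}: \code{symbol}, \code{direction},
#'   \code{logrankP}.
#' @slot edges \code{data.frame}: \code{factor}, \code{event_id},
#'   \code{rho}, \code{p}, \code{sign}.
#' @slot rhoThreshold,pMax The edge thresholds applied.
#' @aliases CorrelationNetwork-class
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
         representation(factors = "data.frame", edges = "data.frame",
                        rhoThreshold = "numeric", pMax = "numeric"))

setValidity("CorrelationNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (nrow(e)) {
    if (any(abs(e$rho) <= object@rhoThreshold))
      msg <- c(msg, "all edges must satisfy |rho| > rhoThreshold")
    if (any(e$p >= object@pMax))
      msg <- c(msg, "all edges must satisfy p < pMax")
    if (!all(e$sign == sign(e$rho)))
      msg <- c(msg, "edge sign must equal sign(rho)")
    if (any(e$factor %in% e$event_id))
      msg <- c(msg, "network must be bipartite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", nrow(object@factors), "splicing factors,",
      length(unique(object@edges$event_id)), "events,",
      nrow(object@edges), "edges (|rho| >", object@rhoThreshold,
      ", p <", object@pMax, ")\n")
  if (nrow(object@edges))
    cat("  positive:", sum(object@edges$sign > 0),
        " negative:", sum(object@edges$sign < 0), "\n")
})

#' Configuration of the synthetic-cohort generator
#'
#' See [simulationConfig()] for construction and the meaning of every slot.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nSamples = "integer", nEvents = "integer",
                        kTrue = "integer", clusterProportions = "numeric",
                        fractionInformative = "numeric",
                        meanLow = "numeric", meanHigh = "numeric",
                        concentration = "numeric", missingRate = "numeric",
                        baselineHazard = "numeric", nPrognostic = "integer",
                        prognosticCoef = "numeric", censoringRate = "numeric",
                        therapyHazardRatio = "numeric",
                        nFactors = "integer", targetsPerFactor = "integer",
                        factorNoiseSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@kTrue > object@nSamples)
    msg <- c(msg, "kTrue must not exceed nSamples")
  if (abs(sum(object@clusterProportions) - 1) > 1e-8)
    msg <- c(msg, "clusterProportions must sum to 1")
  if (length(object@clusterProportions) != object@kTrue)
    msg <- c(msg, "clusterProportions must have length kTrue")
  if (object@meanLow <= 0 || object@meanHigh >= 1 ||
      object@meanLow >= object@meanHigh)
    msg <- c(msg, "need 0 < meanLow < meanHigh < 1")
  for (r in c("fractionInformative", "missingRate", "censoringRate"))
    if (slot(object, r) < 0 || slot(object, r) > 1)
      msg <- c(msg, paste(r, "must lie in [0, 1]"))
  if (length(object@baselineHazard) != object@kTrue)
    msg <- c(msg, "baselineHazard must have length kTrue")
  if (length(object@therapyHazardRatio) != object@kTrue)
    msg <- c(msg, "therapyHazardRatio must have length kTrue")
  if (object@nPrognostic > object@nEvents)
    msg <- c(msg, "nPrognostic must not exceed nEvents")
  if (object@nFactors * object@targetsPerFactor > object@nEvents)
    msg <- c(msg, "nFactors * targetsPerFactor must not exceed nEvents")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,", object@nEvents,
      "events,", object@kTrue, "clusters\n")
  cat("  informative fraction:", object@fractionInformative,
      " prognostic events:", object@nPrognostic,
      " factors:", object@nFactors, "\n")
  cat("  censoring:", object@censoringRate,
      " missing:", object@missingRate, " seed:", object@seed, "\n")
})
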