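## Splicing-factor regulatory network: per-factor prognostic direction
## (mean-split log-rank plus restricted-mean survival comparison),
## factor-event Spearman correlations, thresholded signed edges, and
## GraphML/edge-list export.

#' Default splicing-factor panel
#'
#' Twenty-two splicing factors with recognized prognostic roles in
#' cancer: twelve reported as cancer promoters (CLK2, ELAVL1, HNRNPA2B1,
#' HNRNPH1, PTBP1, SNRPB, SRSF1, SRSF2, SRSF3, SRSF7, SRSF9, SRSF10) and
#' ten as suppressors (CELF2, MBLN2, QKI, RBFOX2, RBM4, RBM5, RBM6,
#' RBM10, RBM11, SRSF5).  Shipped as a plain-text file
#' (\code{extdata/splicing_factors.txt}) that users can replace with
#' their own panel.
#'
#' @return Character vector of 22 gene symbols.
#' @export
defaultSplicingFactors <- function() {
  path <- system.file("extdata", "splicing_factors.txt",
                      package = "SpliceTypes", mustWork = TRUE)
  readLines(path)
}

## Restricted-mean survival time of a KM curve up to tau: the integral of
## the product-limit estimate, carrying the last value forward.
.rmst <- function(times, events, tau) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  t <- c(0, fit$time[fit$time <= tau], tau)
  s <- c(1, fit$surv[fit$time <= tau])
  sum(diff(t) * s)
}

#' Prognostic direction of a splicing factor
#'
#' Dichotomizes the factor's expression at its mean, log-rank tests
#' overall survival between the two groups, and calls the factor
#' \code{"unfavorable"} when the high-expression group has the smaller
#' restricted-mean survival (integrated KM curve up to the shorter of the
#' two groups' last follow-up), else \code{"favorable"}.  Constant
#' expression yields \code{"undetermined"} with \code{p = NA}.
#'
#' @param exprRow Named numeric vector of expression across samples.
#' @param clinical Clinical \code{data.frame} (needs \code{sample_id},
#'   \code{os_months}, \code{os_event}).
#' @param minOverlap Minimum number of usable shared samples (default 10).
#' @return List with \code{direction}, \code{p} (log-rank) and \code{n}.
#' @export
prognosticDirection <- function(exprRow, clinical, minOverlap = 10) {
  ok <- !is.na(clinical$os_months) & !is.na(clinical$os_event)
  use <- intersect(names(exprRow), clinical$sample_id[ok])
  if (length(use) < minOverlap)
    stop("need at least ", minOverlap, " shared samples with survival data")
  x <- exprRow[use]
  cl <- clinical[match(use, clinical$sample_id), ]
  if (stats::var(x) == 0)
    return(list(direction = "undetermined", p = NA_real_,
                n = length(use)))
  g <- ifelse(x >= mean(x), "high", "low")
  if (length(unique(g)) < 2L)
    return(list(direction = "undetermined", p = NA_real_,
                n = length(use)))
  lr <- logrankTest(cl$os_months, cl$os_event, g)
  tau <- min(max(cl$os_months[g == "high"]), max(cl$os_months[g == "low"]))
  rmHigh <- .rmst(cl$os_months[g == "high"], cl$os_event[g == "high"], tau)
  rmLow <- .rmst(cl$os_months[g == "low"], cl$os_event[g == "low"], tau)
  list(direction = if (rmHigh < rmLow) "unfavorable" else "favorable",
       p = lr$p, n = length(use))
}

#' Spearman correlations between splicing factors and events
#'
#' For every (factor, event) pair, Spearman's rho and its two-sided
#' p-value (normal approximation, tie-robust) over the shared samples
#' with non-missing PSI and expression.  Factors absent from the
#' expression matrix are reported in the \code{"skipped"} attribute of
#' the result rather than raising an error.
#'
#' @param expr Genes-x-samples expression matrix.
#' @param psi A \linkS4class{PsiExperiment} or events-x-samples matrix.
#' @param factors Character vector of factor symbols (default: all rows
#'   of \code{expr}).
#' @param events Character vector of event ids (default: all events).
#' @param minOverlap Minimum shared samples per pair (default 10).
#' @return \code{data.frame}: \code{factor}, \code{event_id}, \code{rho},
#'   \code{p}, \code{n}; attribute \code{"skipped"} lists absent factors.
#' @export
sfEventCorrelations <- function(expr, psi, factors = rownames(expr),
                                events = NULL, minOverlap = 10) {
  m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
  if (!is.null(events)) m <- m[events, , drop = FALSE]
  skipped <- setdiff(factors, rownames(expr))
  factors <- intersect(factors, rownames(expr))
  shared <- intersect(colnames(expr), colnames(m))
  if (length(shared) < minOverlap)
    stop("need at least ", minOverlap, " shared samples")
  res <- vector("list", length(factors) * nrow(m))
  i <- 0L
  for (f in factors) {
    x <- expr[f, shared]
    for (e in rownames(m)) {
      y <- m[e, shared]
      ok <- !is.na(x) & !is.na(y)
      i <- i + 1L
      if (sum(ok) < minOverlap) {
        res[[i]] <- data.frame(factor = f, event_id = e, rho = NA_real_,
                               p = NA_real_, n = sum(ok))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman",
                        exact = FALSE))
      res[[i]] <- data.frame(factor = f, event_id = e,
                             rho = unname(ct$estimate), p = ct$p.value,
                             n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(factor = character(), event_id = character(),
                      rho = numeric(), p = numeric(), n = integer())
  attr(out, "skipped") <- skipped
  out
}

#' Build the thresholded correlation network
#'
#' Keeps candidate edges with \code{|rho| > rhoThreshold} (default 0.45;
#' the absolute-value reading, so strong negative correlations qualify)
#' and \code{p < pMax} (default 0.05, uncorrected; set
#' \code{adjust = "BH"} to threshold BH-adjusted q instead).  Edge sign
#' is the sign of rho.  Factor prognostic directions, when supplied, are
#' attached to the factor nodes.
#'
#' @param candidates Candidate table from [sfEventCorrelations()].
#' @param rhoThreshold Absolute correlation threshold (default 0.45).
#' @param pMax P-value threshold (default 0.05).
#' @param directions Optional \code{data.frame} with \code{symbol},
#'   \code{direction}, \code{logrankP} (e.g. from
#'   [prognosticDirection()] applied per factor).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A \linkS4class{CorrelationNetwork}.
#' @export
buildNetwork <- function(candidates, rhoThreshold = 0.45, pMax = 0.05,
                         directions = NULL,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") bhFdr(candidates$p) else candidates$p
  keep <- !is.na(candidates$rho) & !is.na(p) &
    abs(candidates$rho) > rhoThreshold & p < pMax
  nDropped <- sum(!keep)
  edges <- candidates[keep, c("factor", "event_id", "rho", "p"),
                      drop = FALSE]
  edges$p <- p[keep]
  edges$sign <- sign(edges$rho)
  rownames(edges) <- NULL
  message(nrow(edges), " edge(s) kept, ", nDropped,
          " candidate(s) below threshold")
  fac <- unique(candidates$factor)
  factors <- data.frame(symbol = fac,
                        direction = rep("undetermined", length(fac)),
                        logrankP = rep(NA_real_, length(fac)),
                        stringsAsFactors = FALSE)
  if (!is.null(directions)) {
    idx <- match(factors$symbol, directions$symbol)
    hit <- !is.na(idx)
    factors$direction[hit] <- directions$direction[idx[hit]]
    factors$logrankP[hit] <- directions$logrankP[idx[hit]]
  }
  new("CorrelationNetwork", factors = factors, edges = edges,
      rhoThreshold = rhoThreshold, pMax = pMax)
}

#' Convert a CorrelationNetwork to an igraph object
#'
#' Bipartite graph: factor nodes (\code{type = TRUE}, annotated with
#' prognostic direction) and event nodes; edges weighted by rho and
#' carrying their sign and p-value.
#'
#' @param network A \linkS4class{CorrelationNetwork}.
#' @return An \pkg{igraph} graph.
#' @export
asIgraph <- function(network) {
  stopifnot(is(network, "CorrelationNetwork"))
  ev <- unique(network@edges$event_id)
  nodes <- data.frame(
    name = c(network@factors$symbol, ev),
    type = c(rep(TRUE, nrow(network@factors)), rep(FALSE, length(ev))),
    direction = c(network@factors$direction, rep(NA_character_,
                                                 length(ev))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    network@edges[, c("factor", "event_id", "rho", "p", "sign"),
                  drop = FALSE],
    directed = FALSE, vertices = nodes)
}

#' Write a network as GraphML plus a flat edge list
#'
#' Emits \code{<basename>.graphml} and a Cytoscape-importable
#' \code{<basename>_edges.tsv}; both are valid (if empty) for an
#' edgeless network.
#'
#' @param network A \linkS4class{CorrelationNetwork}.
#' @param basename Output path without extension.
#' @return Invisibly, the two written paths.
#' @export
writeNetwork <- function(network, basename) {
  g <- asIgraph(network)
  graphml <- paste0(basename, ".graphml")
  tsv <- paste0(basename, "_edges.tsv")
  igraph::write_graph(g, graphml, format = "graphml")
  utils::write.table(network@edges, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml, tsv))
}

#' End-to-end splicing-factor network construction
#'
#' Convenience wrapper: computes each factor's prognostic direction,
#' correlates factor expression with the supplied event set, and
#' thresholds the edges.
#'
#' @param expr Genes-x-samples expression matrix.
#' @param psi A \linkS4class{PsiExperiment}.
#' @param clinical Clinical \code{data.frame}.
#' @param factors Factor symbols (default [defaultSplicingFactors()]).
#' @param events Event ids to correlate against (e.g. the signature set
#'   of the poorest-prognosis subtype).
#' @param rhoThreshold,pMax,adjust Passed to [buildNetwork()].
#' @return A \linkS4class{CorrelationNetwork}.
#' @export
splicingFactorNetwork <- function(expr, psi, clinical,
                                  factors = defaultSplicingFactors(),
                                  events = NULL, rhoThreshold = 0.45,
                                  pMax = 0.05, adjust = "none") {
  present <- intersect(factors, rownames(expr))
  dirs <- do.call(rbind, lapply(present, function(f) {
    d <- prognosticDirection(expr[f, ], clinical)
    data.frame(symbol = f, direction = d$direction, logrankP = d$p,
               stringsAsFactors = FALSE)
  }))
  cand <- sfEventCorrelations(expr, psi, factors = factors,
                              events = events)
  buildNetwork(cand, rhoThreshold = rhoThreshold, pMax = pMax,
               directions = dirs, adjust = adjust)
}
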