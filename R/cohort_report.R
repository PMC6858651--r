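## Clinical characterization of splicing subtypes: KM summaries,
## annotation cross-tabs with association tests, treatment-stratified
## survival, and a PCA projection of signature PSI.

#' Kaplan-Meier summary per cluster
#'
#' Per-group KM median survival (first time the product-limit estimate
#' drops to <= 0.5) with a log-log 95\% confidence interval, reported as
#' \code{NA} when not reached, plus the global log-rank p across groups.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event).
#' @param labels Group labels, one per sample.
#' @return List with \code{table} (\code{data.frame}: \code{group},
#'   \code{n}, \code{events}, \code{median}, \code{lower}, \code{upper},
#'   survival months rounded to 1 decimal) and \code{logrankP}.
#' @export
kmSummary <- function(times, events, labels) {
  g <- factor(labels)
  if (any(table(g) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ g,
                           conf.type = "log-log")
  st <- summary(fit)$table
  if (is.null(dim(st))) st <- matrix(st, nrow = 1L,
                                     dimnames = list(levels(g), names(st)))
  ## median = first time the product-limit curve drops to <= 0.5 (no
  ## midpoint interpolation at an exact 0.5, unlike survfit's quantile)
  medians <- vapply(levels(g), function(lev) {
    ix <- g == lev
    f1 <- survival::survfit(survival::Surv(times[ix], events[ix]) ~ 1)
    hit <- which(f1$surv <= 0.5 + 1e-12)
    if (length(hit)) f1$time[hit[1L]] else NA_real_
  }, numeric(1L))
  tab <- data.frame(
    group = sub("^g=", "", rownames(st)),
    n = as.integer(st[, "records"]),
    events = as.integer(st[, "events"]),
    median = round(unname(medians[sub("^g=", "", rownames(st))]), 1L),
    lower = round(st[, "0.95LCL"], 1L),
    upper = round(st[, "0.95UCL"], 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  p <- if (nlevels(g) > 1L) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ g)
    as.numeric(stats::pchisq(sd$chisq, df = nlevels(g) - 1L,
                             lower.tail = FALSE))
  } else NA_real_
  list(table = tab, logrankP = p)
}

#' Cross-tabulate clusters against an annotation
#'
#' Counts and row percentages (to 1 decimal) of an annotation within each
#' cluster, with \code{"unknown"}/\code{NA} excluded from denominators
#' and reported separately.  Association is tested by chi-square, falling
#' back to Fisher's exact test when any expected cell count is below 5.
#'
#' @param labels Cluster labels, one per sample.
#' @param annotation Categorical annotation, one per sample.
#' @return List with \code{counts} (clusters x levels), \code{percent}
#'   (same shape, 1 decimal; rows sum to ~100), \code{unknown} (per
#'   cluster count excluded), \code{p} and \code{test}
#'   (\code{"chi-square"} or \code{"fisher"}).
#' @examples
#' crosstabProportions(rep(c(1, 2), each = 10),
#'                     rep(c("a", "b", "a", "a"), 5))
#' @export
crosstabProportions <- function(labels, annotation) {
  known <- !is.na(annotation) & annotation != "unknown"
  unknown <- table(factor(labels)[!known])
  counts <- table(factor(labels[known]), factor(annotation[known]))
  denom <- rowSums(counts)
  percent <- round(100 * sweep(unclass(counts), 1L, pmax(denom, 1L), "/"),
                   1L)
  res <- if (all(dim(counts) >= 2L) && sum(counts) > 0L) {
    cs <- suppressWarnings(stats::chisq.test(counts))
    if (any(cs$expected < 5)) {
      ft <- tryCatch(stats::fisher.test(counts),
                     error = function(e)
                       stats::fisher.test(counts, simulate.p.value = TRUE,
                                          B = 1e4))
      list(p = ft$p.value, test = "fisher")
    } else list(p = cs$p.value, test = "chi-square")
  } else list(p = NA_real_, test = NA_character_)
  list(counts = unclass(counts), percent = percent,
       unknown = unknown, p = res$p, test = res$test)
}

#' Treatment-stratified survival per cluster
#'
#' Within each cluster, log-rank comparison of samples on standard
#' therapy (concurrent chemoradiotherapy flag \code{"1"}) versus
#' nonstandard (\code{"0"}).  Clusters with fewer than 2 usable samples
#' in either arm are skipped with a note.
#'
#' @param clinical Clinical \code{data.frame} (needs \code{os_months},
#'   \code{os_event}, \code{standard_therapy}).
#' @param labels Cluster labels named by sample id (or aligned with the
#'   clinical rows).
#' @return \code{data.frame}: \code{cluster}, \code{nStandard},
#'   \code{nNonstandard}, \code{p}, \code{note}.
#' @export
treatmentStratifiedSurvival <- function(clinical, labels) {
  labels <- .alignLabels(labels, clinical$sample_id)
  out <- lapply(sort(unique(labels)), function(cl) {
    ix <- which(labels == cl)
    th <- clinical$standard_therapy[ix]
    ok <- th %in% c("0", "1") & !is.na(clinical$os_months[ix]) &
      !is.na(clinical$os_event[ix])
    nStd <- sum(th[ok] == "1"); nNon <- sum(th[ok] == "0")
    if (nStd < 2L || nNon < 2L)
      return(data.frame(cluster = cl, nStandard = nStd,
                        nNonstandard = nNon, p = NA_real_,
                        note = "skipped: arm with < 2 samples",
                        stringsAsFactors = FALSE))
    lr <- logrankTest(clinical$os_months[ix][ok],
                      clinical$os_event[ix][ok], th[ok])
    data.frame(cluster = cl, nStandard = nStd, nNonstandard = nNon,
               p = lr$p, note = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' PCA projection of samples on signature events
#'
#' Centered (unscaled) PCA of the samples on the supplied signature PSI
#' rows; returns the first two components with a deterministic sign
#' convention (the largest-magnitude loading of each component is made
#' positive).
#'
#' @param m Events-x-samples matrix without missing values (signature
#'   rows are complete by construction), >= 2 events and >= 3 samples.
#' @return List with \code{coords} (samples x 2), \code{varExplained}
#'   (fractions for PC1/PC2).
#' @export
pcaProjection <- function(m) {
  m <- if (is(m, "PsiExperiment")) psiValues(m) else as.matrix(m)
  if (anyNA(m)) stop("matrix must not contain missing values")
  if (nrow(m) < 2L || ncol(m) < 3L)
    stop("need at least 2 events and 3 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(coords = scores, varExplained = ve)
}

#' Full clinical report for a clustering
#'
#' Bundles the KM summary across clusters, annotation cross-tabs for
#' every categorical clinical column, the treatment-stratified log-rank
#' table, and (when signature event ids are given) the PCA projection.
#' Percentages are checked to recompute from their counts before the
#' report is returned.
#'
#' @param psi A \linkS4class{PsiExperiment}.
#' @param clinical Clinical \code{data.frame}.
#' @param labels Cluster labels named by sample id.
#' @param signatureIds Optional character vector of signature event ids
#'   for the PCA panel.
#' @param annotations Which clinical columns to cross-tabulate (default:
#'   all recognised categorical columns present).
#' @return List with \code{km}, \code{crosstabs} (named list),
#'   \code{treatment}, \code{pca} (or \code{NULL}).
#' @export
clusterReport <- function(psi, clinical, labels, signatureIds = NULL,
                          annotations = NULL) {
  use <- intersect(names(labels), clinical$sample_id)
  use <- use[!is.na(clinical$os_months[match(use, clinical$sample_id)]) &
               !is.na(clinical$os_event[match(use, clinical$sample_id)])]
  cl <- clinical[match(use, clinical$sample_id), ]
  lab <- labels[use]
  km <- kmSummary(cl$os_months, cl$os_event, lab)
  if (is.null(annotations))
    annotations <- intersect(setdiff(.CLINICAL_CATEGORICAL,
                                     "standard_therapy"),
                             colnames(clinical))
  crosstabs <- lapply(annotations, function(a)
    crosstabProportions(lab, cl[[a]]))
  names(crosstabs) <- annotations
  ## self-consistency: every percentage recomputes from its counts
  for (ct in crosstabs) {
    denom <- pmax(rowSums(ct$counts), 1L)
    stopifnot(all(abs(ct$percent - round(100 * ct$counts / denom, 1L))
                  < 1e-9))
  }
  treatment <- if ("standard_therapy" %in% colnames(clinical))
    treatmentStratifiedSurvival(cl, lab) else NULL
  pca <- if (!is.null(signatureIds) && length(signatureIds) >= 2L) {
    sub <- psiValues(psi)[signatureIds, use, drop = FALSE]
    pcaProjection(sub)
  } else NULL
  list(km = km, crosstabs = crosstabs, treatment = treatment, pca = pca)
}
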