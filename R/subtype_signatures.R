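## Subtype-specific signature calling (multi-group fold + FDR rule),
## two-group (e.g. IDH-status) related events, and unit rescaling of PSI
## rows for heatmap export.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment of a vector of p-values (monotone in rank order,
#' each q at least its p).
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted q-values, same length/order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

## Two-sided Mann-Whitney U p-value, normal approximation with tie
## correction (continuity-corrected), as wilcox.test(exact = FALSE) does.
.mannWhitneyP <- function(x, y) {
  stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                     correct = TRUE)$p.value
}

#' Call subtype-specific signature events
#'
#' An event is a signature of subtype s when its mean PSI in s is at least
#' \code{fold} times its mean in \emph{every} other subtype (default 1.30,
#' i.e. "30\% higher", read as a relative fold change) \emph{and} the
#' BH-adjusted two-sided Mann-Whitney q-value of s versus each other
#' subtype is below \code{fdr}.  The BH family is the full set of event x
#' comparison tests in one pass.  The fold rule makes signature sets
#' provably disjoint across subtypes (mutual fold >= 1.3 in both
#' directions is impossible for positive means); this is asserted on every
#' run.
#'
#' @param psi A \linkS4class{PsiExperiment} or events-x-samples matrix.
#' @param labels Subtype labels, one per sample (named or in column
#'   order); every subtype needs >= 2 samples.
#' @param fold Relative fold threshold (default 1.30).
#' @param fdr FDR level (default 0.05).
#' @return A \linkS4class{SignatureSet}.
#' @export
subtypeSpecificEvents <- function(psi, labels, fold = 1.30, fdr = 0.05) {
  m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
  labels <- .alignLabels(labels, colnames(m))
  groups <- split(seq_along(labels), labels)
  if (length(groups) < 2L) stop("need at least 2 subtypes")
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small))
    stop("subtype(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  subtypes <- names(groups)
  means <- vapply(groups, function(ix)
    rowMeans(m[, ix, drop = FALSE], na.rm = TRUE), numeric(nrow(m)))
  if (nrow(m) == 1L) means <- matrix(means, nrow = 1L,
                                     dimnames = list(rownames(m), subtypes))

  top <- subtypes[max.col(means, ties.method = "first")]
  nCmp <- length(subtypes) - 1L
  pmat <- matrix(NA_real_, nrow(m), nCmp)
  foldOk <- logical(nrow(m))
  foldVsBest <- rep(NA_real_, nrow(m))
  for (e in seq_len(nrow(m))) {
    s <- top[e]
    others <- setdiff(subtypes, s)
    foldVsBest[e] <- means[e, s] / max(means[e, others])
    foldOk[e] <- all(means[e, s] >= fold * means[e, others])
    xs <- m[e, groups[[s]]]
    pmat[e, ] <- vapply(others, function(t)
      .mannWhitneyP(xs, m[e, groups[[t]]]), numeric(1L))
  }
  q <- matrix(bhFdr(as.vector(pmat)), nrow(m), nCmp)
  maxQ <- apply(q, 1L, max)
  assigned <- foldOk & maxQ < fdr
  tab <- data.frame(event_id = rownames(m),
                    subtype = ifelse(assigned, top, NA_character_),
                    foldVsBest = foldVsBest, maxQ = maxQ,
                    assigned = assigned, stringsAsFactors = FALSE)
  ## disjointness is structural; verify anyway
  stopifnot(!anyDuplicated(tab$event_id[tab$assigned]))
  new("SignatureSet", table = tab, subtypeMeans = means,
      fold = fold, fdr = fdr)
}

#' Call two-group (e.g. IDH-status) related events
#'
#' An event is selected when the larger of the two group means is at least
#' \code{fold} times the smaller (default 2; a pseudocount of
#' \code{eps = 1e-3} is added to both means so near-zero means do not
#' produce unbounded ratios) and the BH-adjusted two-sided Mann-Whitney q
#' across all events is below \code{fdr}.  The rule is symmetric in the
#' group labelling: the selected set is invariant, directions flip.
#'
#' @param psi A \linkS4class{PsiExperiment} or events-x-samples matrix.
#' @param group Two-level annotation, one value per sample (e.g.
#'   IDH mutant/wild-type); both levels need >= 2 samples.  Values of
#'   \code{"unknown"}/\code{NA} are excluded.
#' @param fold Fold threshold on the group-mean ratio (default 2.0).
#' @param fdr FDR level (default 0.05).
#' @param eps Pseudocount added to both means (default 1e-3).
#' @return \code{data.frame}: \code{event_id}, \code{meanA}, \code{meanB}
#'   (means for the first/second group level), \code{ratio}, \code{q},
#'   \code{selected}, \code{direction} (group level with the higher mean,
#'   \code{NA} when not selected).
#' @export
twoGroupEvents <- function(psi, group, fold = 2.0, fdr = 0.05,
                           eps = 1e-3) {
  m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
  group <- .alignLabels(group, colnames(m))
  keep <- !is.na(group) & group != "unknown"
  m <- m[, keep, drop = FALSE]
  group <- group[keep]
  lev <- unique(group)
  if (length(lev) != 2L) stop("group must have exactly two levels")
  ia <- which(group == lev[1L]); ib <- which(group == lev[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least 2 samples")
  meanA <- rowMeans(m[, ia, drop = FALSE], na.rm = TRUE)
  meanB <- rowMeans(m[, ib, drop = FALSE], na.rm = TRUE)
  ratio <- (pmax(meanA, meanB) + eps) / (pmin(meanA, meanB) + eps)
  p <- vapply(seq_len(nrow(m)), function(e)
    .mannWhitneyP(m[e, ia], m[e, ib]), numeric(1L))
  q <- bhFdr(p)
  selected <- ratio >= fold & q < fdr
  data.frame(event_id = rownames(m), meanA = meanA, meanB = meanB,
             ratio = ratio, q = q, selected = selected,
             direction = ifelse(selected,
                                ifelse(meanA >= meanB, lev[1L], lev[2L]),
                                NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rescale PSI rows to the unit interval
#'
#' Per event row: \eqn{(x - min) / (max - min)}.  Constant rows map to 0;
#' missing values stay missing.  Intended for heatmap display.
#'
#' @param m Events-x-samples matrix (or \linkS4class{PsiExperiment}).
#' @return Matrix of the same shape.
#' @examples
#' rescaleUnit(matrix(c(0.2, 0.4, 0.6), 1))  # 0, 0.5, 1
#' @export
rescaleUnit <- function(m) {
  m <- if (is(m, "PsiExperiment")) psiValues(m) else as.matrix(m)
  t(apply(m, 1L, function(x) {
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1L]) || rng[1L] == rng[2L])
      return(ifelse(is.na(x), NA_real_, 0))
    (x - rng[1L]) / (rng[2L] - rng[1L])
  }))
}

## Match a per-sample vector to a sample ordering, by names when present.
.alignLabels <- function(x, samples) {
  if (!is.null(names(x)) && !is.null(samples)) {
    miss <- setdiff(samples, names(x))
    if (length(miss))
      stop("labels missing for sample(s): ",
           paste(utils::head(miss, 3L), collapse = ", "))
    x <- x[samples]
  } else if (length(x) != length(samples)) {
    stop("labels length does not match the number of samples")
  }
  x
}
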