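## Genome-wide PSI survival screening: mean-split dichotomization,
## inclusion filtering, per-event log-rank testing, prognostic calls and
## per-category tallies.

#' Dichotomize a PSI row at its arithmetic mean
#'
#' Samples with PSI greater than or equal to the row mean are labelled
#' \code{"high"}, the rest \code{"low"}.  Ties at the mean deliberately go
#' to the high group so the split is deterministic; a constant row
#' therefore yields an all-high split (handled downstream by
#' [inclusionFilter()]).
#'
#' @param psiRow Numeric vector of PSI values without missing entries.
#' @return Character vector of \code{"low"}/\code{"high"} labels, named
#'   like \code{psiRow}.
#' @examples
#' dichotomizeByMean(c(s1 = 0.1, s2 = 0.2, s3 = 0.8, s4 = 0.9))
#' @export
dichotomizeByMean <- function(psiRow) {
  if (anyNA(psiRow))
    stop("psiRow must not contain missing values; filter first")
  stats::setNames(ifelse(psiRow >= mean(psiRow), "high", "low"),
                  names(psiRow))
}

#' Per-event inclusion filter for the survival screen
#'
#' An event is screened only if (1) its PSI is non-missing for every
#' sample and (2) both mean-split groups contain at least
#' \code{ceiling(minFrac * nTotal)} samples (5\% of the cohort by
#' default).  \code{minGroup} overrides the computed threshold with a
#' fixed count.
#'
#' @param psiRow Numeric PSI vector (may contain \code{NA}).
#' @param nTotal Total cohort size (defaults to \code{length(psiRow)}).
#' @param minFrac Minimum group size as a fraction of \code{nTotal}
#'   (default 0.05).
#' @param minGroup Optional fixed minimum group size overriding
#'   \code{ceiling(minFrac * nTotal)}.
#' @return List with \code{included} (logical) and \code{reason}
#'   (\code{NA}, \code{"missing-psi"} or \code{"small-group"}).
#' @export
inclusionFilter <- function(psiRow, nTotal = length(psiRow),
                            minFrac = 0.05, minGroup = NULL) {
  if (anyNA(psiRow))
    return(list(included = FALSE, reason = "missing-psi"))
  thr <- if (is.null(minGroup)) ceiling(minFrac * nTotal)
         else as.integer(minGroup)
  g <- dichotomizeByMean(psiRow)
  if (min(sum(g == "low"), sum(g == "high")) < thr)
    return(list(included = FALSE, reason = "small-group"))
  list(included = TRUE, reason = NA_character_)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Unstratified, unweighted log-rank comparison of two survival curves via
#' [survival::survdiff()]; the chi-square statistic has 1 degree of
#' freedom and the two-sided p-value comes from its chi-square
#' distribution.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event observed, 0 = censored).
#' @param groups Two-level grouping vector; both levels must be present.
#' @return List with \code{chisq} and \code{p}.
#' @examples
#' logrankTest(c(1, 2, 3, 4, 5, 6), rep(1, 6),
#'             rep(c("a", "b"), each = 3))
#' @export
logrankTest <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(droplevels(g)) != 2L)
    stop("log-rank test needs exactly two non-empty groups; ",
         "filter degenerate events first")
  if (any(times < 0)) stop("times must be non-negative")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g, rho = 0)
  chisq <- as.numeric(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Screen every splicing event for prognostic significance
#'
#' For each event: apply the inclusion filter, split samples at the mean
#' PSI, and log-rank test overall survival between the low and high
#' groups.  Events with p below \code{alpha} (default 0.01, no multiple
#' testing correction) are called prognostic.  Samples are the
#' intersection of the PSI columns and the clinical rows with non-missing
#' survival data; dropped counts are reported via \code{message()}.
#'
#' @param psi A \linkS4class{PsiExperiment}.
#' @param clinical Clinical \code{data.frame} with \code{sample_id},
#'   \code{os_months}, \code{os_event}.
#' @param alpha Prognostic p-value threshold (default 0.01).
#' @param minFrac Minimum group-size fraction (default 0.05).
#' @param minGroup Optional fixed minimum group size (see
#'   [inclusionFilter()]).
#' @return \code{data.frame}, one row per event: \code{event_id},
#'   \code{symbol}, \code{splice_type}, \code{nLow}, \code{nHigh},
#'   \code{chisq}, \code{p}, \code{included}, \code{reason},
#'   \code{prognostic}.
#' @export
screenEvents <- function(psi, clinical, alpha = 0.01, minFrac = 0.05,
                         minGroup = NULL) {
  stopifnot(is(psi, "PsiExperiment"))
  ok <- !is.na(clinical$os_months) & !is.na(clinical$os_event)
  nDropped <- sum(!ok)
  use <- intersect(colnames(psi), clinical$sample_id[ok])
  if (length(use) == 0L)
    stop("no overlapping samples with survival data between psi and clinical")
  if (nDropped)
    message(nDropped, " sample(s) dropped for missing survival data")
  message(length(use), " samples used for screening")
  m <- psiValues(psi)[, use, drop = FALSE]
  cl <- clinical[match(use, clinical$sample_id), ]
  n <- length(use)

  rd <- rowData(psi)
  out <- data.frame(event_id = rownames(m), symbol = rd$symbol,
                    splice_type = rd$splice_type,
                    nLow = NA_integer_, nHigh = NA_integer_,
                    chisq = NA_real_, p = NA_real_,
                    included = FALSE, reason = NA_character_,
                    prognostic = FALSE, stringsAsFactors = FALSE)
  for (e in seq_len(nrow(m))) {
    row <- m[e, ]
    f <- inclusionFilter(row, nTotal = n, minFrac = minFrac,
                         minGroup = minGroup)
    out$reason[e] <- f$reason
    if (!f$included) next
    g <- dichotomizeByMean(row)
    out$included[e] <- TRUE
    out$nLow[e] <- sum(g == "low")
    out$nHigh[e] <- sum(g == "high")
    lr <- logrankTest(cl$os_months, cl$os_event, g)
    out$chisq[e] <- lr$chisq
    out$p[e] <- lr$p
    out$prognostic[e] <- lr$p < alpha
  }
  out
}

#' Tally prognostic events per splice category
#'
#' @param results A screen-result \code{data.frame} (from [screenEvents()])
#'   or any \code{data.frame} with a \code{splice_type} column and,
#'   optionally, a logical \code{prognostic} column (absent means count
#'   all rows).
#' @return Named integer vector over the 7 categories (canonical order)
#'   plus a \code{total} element equal to their sum.
#' @examples
#' categorizeCounts(data.frame(splice_type = c("ES", "ES", "AT"),
#'                             prognostic = c(TRUE, FALSE, TRUE)))
#' @export
categorizeCounts <- function(results) {
  keep <- if ("prognostic" %in% colnames(results)) results$prognostic
          else rep(TRUE, nrow(results))
  tab <- table(factor(results$splice_type[keep],
                      levels = spliceCategories()))
  counts <- stats::setNames(as.integer(tab), spliceCategories())
  c(counts, total = sum(counts))
}
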