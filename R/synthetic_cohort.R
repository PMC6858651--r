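## Synthetic PSI cohort generator with known ground truth: planted splicing
## subtypes (beta-distributed PSI with cluster-specific means), planted
## prognostic events (exponential survival with PSI-dependent log-hazard),
## and planted splicing-factor regulation (factor expression a monotone
## function of mean target-event PSI).

#' Configure the synthetic-cohort generator
#'
#' All downstream stages of the pipeline can be exercised on cohorts drawn
#' from this generator, with the planted structure returned as ground truth.
#'
#' @param nSamples Number of samples (default 300, a mid-sized tumour
#'   cohort).
#' @param nEvents Number of splicing events (default 500).
#' @param kTrue Number of planted splicing subtypes (default 3).
#' @param clusterProportions Mixing proportions, length \code{kTrue},
#'   summing to 1 (default equal).
#' @param fractionInformative Fraction of events whose beta mean differs
#'   across clusters (default 0.3); the rest share one population mean.
#' @param meanLow,meanHigh The two cluster-mean levels used for informative
#'   events (defaults 0.3 / 0.7, i.e. a mean gap of 0.4).
#' @param concentration Beta concentration (shape1 + shape2); larger means
#'   tighter within-cluster PSI (default 50).
#' @param missingRate Fraction of PSI cells set missing (default 0.05).
#' @param baselineHazard Per-cluster exponential baseline hazard per month
#'   (default \code{c(0.08, 0.04, 0.02)} recycled/truncated to
#'   \code{kTrue}, i.e. median survival roughly 9 to 35 months).
#' @param nPrognostic Number of planted prognostic events (default 50).
#' @param prognosticCoef Absolute per-event log-hazard coefficient on PSI
#'   (default 1.5); planted signs alternate.
#' @param censoringRate Target probability a sample is censored (default
#'   0.3); achieved exactly in expectation via an independent exponential
#'   censoring time matched per-sample to the event hazard.
#' @param therapyHazardRatio Per-cluster multiplicative hazard effect of
#'   standard therapy (default all 1 = no effect; e.g. 0.5 halves the
#'   hazard of treated samples in that cluster).
#' @param nFactors Number of splicing factors (default 10).
#' @param targetsPerFactor Planted target events per factor (default 5).
#' @param factorNoiseSd Gaussian noise s.d. on the factor link scale
#'   (default 0.1).
#' @param seed Integer RNG seed; the same config yields byte-identical
#'   cohorts.
#' @return A \linkS4class{SimulationConfig}.
#' @seealso [simulateCohort()]
#' @export
simulationConfig <- function(nSamples = 300L, nEvents = 500L, kTrue = 3L,
                             clusterProportions = rep(1 / kTrue, kTrue),
                             fractionInformative = 0.3,
                             meanLow = 0.3, meanHigh = 0.7,
                             concentration = 50, missingRate = 0.05,
                             baselineHazard = rep_len(c(0.08, 0.04, 0.02), kTrue),
                             nPrognostic = 50L, prognosticCoef = 1.5,
                             censoringRate = 0.3,
                             therapyHazardRatio = rep(1, kTrue),
                             nFactors = 10L, targetsPerFactor = 5L,
                             factorNoiseSd = 0.1, seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nEvents = as.integer(nEvents),
      kTrue = as.integer(kTrue),
      clusterProportions = as.numeric(clusterProportions),
      fractionInformative = fractionInformative,
      meanLow = meanLow, meanHigh = meanHigh,
      concentration = concentration, missingRate = missingRate,
      baselineHazard = as.numeric(baselineHazard),
      nPrognostic = as.integer(nPrognostic),
      prognosticCoef = prognosticCoef, censoringRate = censoringRate,
      therapyHazardRatio = as.numeric(therapyHazardRatio),
      nFactors = as.integer(nFactors),
      targetsPerFactor = as.integer(targetsPerFactor),
      factorNoiseSd = factorNoiseSd, seed = as.integer(seed))
}

## Category frequencies loosely shaped like genome-wide splice-event
## detection (exon skips dominate, mutually exclusive exons are rare).
.CATEGORY_PROB <- c(ES = 0.57, RI = 0.04, AP = 0.15, AT = 0.11,
                    AD = 0.06, AA = 0.07, ME = 0.004)

#' Simulate a PSI cohort with known ground truth
#'
#' Draws a cohort under the model described in the package vignette:
#' cluster labels from \code{clusterProportions}; PSI per event per cluster
#' from beta distributions (informative events have cluster-specific means
#' at the \code{meanLow}/\code{meanHigh} levels, uninformative events one
#' shared mean); overall-survival times from an exponential whose log
#' hazard is the cluster baseline plus \eqn{\sum_e \beta_e \, PSI_e}
#' (centered) over the planted prognostic events, times a per-cluster
#' therapy effect for treated samples; independent exponential censoring
#' matched to the configured censoring rate; splicing-factor expression as
#' \code{exp(intercept + slope * meanTargetPSI + noise)}, where the
#' targets of each factor additionally co-vary across samples through a
#' shared latent regulatory activity (a logit-scale shift of their beta
#' means) as events under one trans-acting regulator do; missing PSI
#' cells at \code{missingRate}.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A list with elements \code{psi} (\linkS4class{PsiExperiment}),
#'   \code{clinical} (\code{data.frame}), \code{expression} (factors x
#'   samples matrix) and \code{truth} (list: \code{clusters},
#'   \code{prognosticEvents}, \code{informative}, \code{factorMap}).
#' @examples
#' coh <- simulateCohort(simulationConfig(nSamples = 40, nEvents = 30,
#'                                        seed = 7))
#' coh$psi
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples; p <- config@nEvents; k <- config@kTrue

  sampleIds <- sprintf("S%04d", seq_len(n))
  clusters <- sample(seq_len(k), n, replace = TRUE,
                     prob = config@clusterProportions)
  names(clusters) <- sampleIds

  events <- data.frame(
    symbol = sprintf("GENE%04d", seq_len(p)),
    as_id = seq_len(p),
    splice_type = sample(names(.CATEGORY_PROB), p, replace = TRUE,
                         prob = .CATEGORY_PROB),
    exon_label = paste0("exon", sample(2:40, p, replace = TRUE)),
    stringsAsFactors = FALSE)
  ids <- eventId(events)

  ## cluster-mean profiles: k x p matrix of beta means
  nInfo <- round(config@fractionInformative * p)
  informative <- c(rep(TRUE, nInfo), rep(FALSE, p - nInfo))
  M <- matrix(0, k, p)
  for (e in seq_len(p)) {
    if (informative[e]) {
      ## at least one cluster high and one low so the between-cluster
      ## mean range is strictly positive
      nHigh <- sample(seq_len(k - 1L), 1L)
      high <- sample(seq_len(k), nHigh)
      M[, e] <- config@meanLow
      M[high, e] <- config@meanHigh
    } else {
      M[, e] <- stats::runif(1, 0.2, 0.8)
    }
  }

  ## planted prognostic events: prefer uninformative events so the PSI
  ## effect on hazard is separable from the cluster effect; hazard signs
  ## are blocked (first half +, second half -) so each factor's target
  ## block below shares one direction of effect
  pool <- c(which(!informative), which(informative))
  nProg <- config@nPrognostic
  progIdx <- pool[seq_len(nProg)]
  progSign <- if (nProg) c(rep(1, ceiling(nProg / 2)),
                           rep(-1, floor(nProg / 2))) else integer(0)
  coef <- numeric(p)
  coef[progIdx] <- progSign * config@prognosticCoef

  ## per-factor latent regulatory activity: the targets of one factor
  ## co-vary across samples through a shared logit-scale shift, the way
  ## events under a common trans-acting regulator do (cluster-independent,
  ## so between-cluster population means are untouched)
  nf <- config@nFactors
  tpf <- config@targetsPerFactor
  targetPool <- c(progIdx, setdiff(seq_len(p), progIdx))
  factorTargets <- lapply(seq_len(nf), function(f)
    targetPool[(f - 1L) * tpf + seq_len(tpf)])
  latent <- matrix(stats::rnorm(nf * n), nf, n)
  couplingSd <- 0.8

  ## PSI draws (events x samples)
  cc <- config@concentration
  mu <- t(M[clusters, , drop = FALSE])               # p x n
  for (f in seq_len(nf)) {
    tgt <- factorTargets[[f]]
    shift <- rep(couplingSd * latent[f, ], each = length(tgt))
    mu[tgt, ] <- stats::plogis(stats::qlogis(mu[tgt, , drop = FALSE]) +
                                 shift)
  }
  psi <- matrix(stats::rbeta(n * p, mu * cc, (1 - mu) * cc),
                nrow = p, ncol = n, dimnames = list(ids, sampleIds))

  therapy <- stats::rbinom(n, 1, 0.5)
  popMean <- as.numeric(config@clusterProportions %*% M)
  lp <- as.numeric(coef %*% (psi - popMean))
  hazard <- config@baselineHazard[clusters] * exp(lp) *
    config@therapyHazardRatio[clusters]^therapy
  tEvent <- stats::rexp(n, rate = hazard)
  cr <- config@censoringRate
  if (cr > 0) {
    tCens <- stats::rexp(n, rate = hazard * cr / (1 - cr))
    osEvent <- as.integer(tEvent <= tCens)
    osMonths <- pmin(tEvent, tCens)
  } else {
    osEvent <- rep(1L, n)
    osMonths <- tEvent
  }

  ## splicing factors: expression = exp(1 + sign * 3 * meanTargetPSI + eps)
  factorIds <- sprintf("SF%02d", seq_len(nf))
  factorMap <- vector("list", nf)
  names(factorMap) <- factorIds
  expr <- matrix(0, nf, n, dimnames = list(factorIds, sampleIds))
  for (f in seq_len(nf)) {
    tgt <- factorTargets[[f]]
    sgn <- if (f %% 2L == 1L) 1 else -1
    meanTarget <- colMeans(psi[tgt, , drop = FALSE])
    expr[f, ] <- exp(1 + sgn * 3 * meanTarget +
                       stats::rnorm(n, 0, config@factorNoiseSd))
    ## direction of the factor's association with hazard: sign of the
    ## average (link sign x event log-hazard coefficient) over its targets
    hazAssoc <- sgn * mean(coef[tgt])
    factorMap[[f]] <- list(targets = ids[tgt], sign = sgn,
                           direction = if (hazAssoc > 0) "unfavorable"
                                       else if (hazAssoc < 0) "favorable"
                                       else "undetermined")
  }

  ## clinical annotations, cluster-linked so cross-tabs have signal
  gbmLike <- clusters == 1L
  rb <- function(pTrue, yes, no)
    ifelse(stats::runif(n) < pTrue, yes, no)
  clinical <- data.frame(
    sample_id = sampleIds,
    os_months = osMonths,
    os_event = osEvent,
    age = round(stats::rnorm(n, ifelse(gbmLike, 60, 42), 10), 1),
    karnofsky = sample(c(100, 90, 80, 70, 60), n, replace = TRUE),
    grade = ifelse(gbmLike, "G4", rb(0.5, "G2", "G3")),
    histology = ifelse(gbmLike, "Glioblastoma",
                       rb(0.5, "Astrocytoma", "Oligodendroglioma")),
    idh_status = rb(ifelse(gbmLike, 0.08, 0.85), "Mutant", "WT"),
    codel_1p19q = rb(ifelse(gbmLike, 0.02, 0.35), "codel", "non-codel"),
    mgmt_status = rb(ifelse(gbmLike, 0.35, 0.8), "Methylated",
                     "Unmethylated"),
    tert_status = rb(ifelse(gbmLike, 0.8, 0.5), "Expressed",
                     "Not-expressed"),
    atrx_status = rb(ifelse(gbmLike, 0.1, 0.3), "Mutant", "WT"),
    chr7gain_chr10loss = rb(ifelse(gbmLike, 0.6, 0.05), "Gain-loss",
                            "No-CNA"),
    chr19_20_gain = rb(ifelse(gbmLike, 0.12, 0.03), "Gain", "No-gain"),
    standard_therapy = as.character(therapy),
    stringsAsFactors = FALSE)
  rownames(clinical) <- sampleIds

  if (config@missingRate > 0) {
    nMiss <- round(config@missingRate * length(psi))
    psi[sample(length(psi), nMiss)] <- NA_real_
  }

  list(psi = PsiExperiment(psi, events),
       clinical = clinical,
       expression = expr,
       truth = list(clusters = clusters,
                    prognosticEvents = data.frame(
                      event_id = ids[progIdx], sign = progSign,
                      stringsAsFactors = FALSE),
                    informative = stats::setNames(informative, ids),
                    factorMap = factorMap))
}

#' Write a simulated cohort to disk
#'
#' Writes the PSI matrix, clinical table and expression matrix in the
#' package's tabular dialects, plus ground-truth files (cluster labels,
#' planted prognostic events, factor-target map).
#'
#' @param cohort A list as returned by [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("psi.tsv", "clinical.tsv", "expression.tsv",
                            "truth_clusters.tsv", "truth_prognostic.tsv",
                            "truth_factors.tsv"))
  writePsiTable(cohort$psi, paths[1L])
  writeClinicalTable(cohort$clinical, paths[2L])
  writeExpressionTable(cohort$expression, paths[3L])
  utils::write.table(data.frame(sample_id = names(cohort$truth$clusters),
                                cluster = cohort$truth$clusters),
                     paths[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$prognosticEvents, paths[5L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fm <- cohort$truth$factorMap
  utils::write.table(data.frame(
    factor = rep(names(fm), vapply(fm, function(x) length(x$targets), 1L)),
    event_id = unlist(lapply(fm, `[[`, "targets"), use.names = FALSE),
    sign = rep(vapply(fm, `[[`, 1, "sign"),
               vapply(fm, function(x) length(x$targets), 1L)),
    direction = rep(vapply(fm, `[[`, "", "direction"),
                    vapply(fm, function(x) length(x$targets), 1L))),
    paths[6L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
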