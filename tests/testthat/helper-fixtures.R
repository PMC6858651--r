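# Shared fixture builders: everything is generated in code at test time.

# PsiExperiment from a bare matrix; event identities are synthesized.
makePsi <- function(values, spliceTypes = NULL) {
  values <- as.matrix(values)
  p <- nrow(values)
  if (is.null(spliceTypes))
    spliceTypes <- rep_len(spliceCategories(), p)
  events <- data.frame(symbol = sprintf("G%03d", seq_len(p)),
                       as_id = seq_len(p), splice_type = spliceTypes,
                       exon_label = paste0("exon", seq_len(p) + 1L),
                       stringsAsFactors = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  PsiExperiment(values, events)
}

# Small planted-subtype cohort for end-to-end tests.
smallCohort <- function(seed = 1, n = 60, nEvents = 30, k = 2,
                        missingRate = 0, ...) {
  simulateCohort(simulationConfig(
    nSamples = n, nEvents = nEvents, kTrue = k,
    baselineHazard = rep_len(c(0.08, 0.03, 0.02), k),
    therapyHazardRatio = rep(1, k),
    clusterProportions = rep(1 / k, k),
    nPrognostic = min(10L, nEvents), nFactors = 2L,
    targetsPerFactor = max(1L, min(5L, nEvents %/% 4L)),
    missingRate = missingRate, seed = seed, ...))
}

# Adjusted Rand index between two labelings (direct contingency formula),
# used as the independent oracle for cluster-recovery checks.
ariOracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}
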