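test_that("KM medians match product-limit hand calculations", {
  # 9 uncensored deaths at t = 1..9: median is the sample median, 5
  km <- kmSummary(1:9, rep(1, 9), rep("g", 9))
  expect_equal(km$table$median, 5)
  expect_true(is.na(km$logrankP))

  # all censored: the curve never drops -> median not reached
  km2 <- kmSummary(c(3, 6, 9), c(0, 0, 0), rep("g", 3))
  expect_true(is.na(km2$table$median))

  # censored worked example, deaths at 2 and 4, censorings at 3, 5, 6:
  # S(2) = 4/5 = 0.8; at t = 4 three remain, S(4) = 0.8 * 2/3 = 0.533;
  # the curve never reaches 0.5 -> median not reached
  km3 <- kmSummary(c(2, 3, 4, 5, 6), c(1, 0, 1, 0, 0), rep("g", 5))
  expect_true(is.na(km3$table$median))

  # deaths 2, 3, 4 with one censoring at 5: S(2) = 0.75, S(3) = 0.5,
  # so the first time S <= 0.5 is t = 3
  km4 <- kmSummary(c(2, 3, 4, 5), c(1, 1, 1, 0), rep("g", 4))
  expect_equal(km4$table$median, 3)

  # unused factor levels are dropped rather than treated as empty groups
  km5 <- kmSummary(1:4, rep(1, 4), factor(rep("a", 4),
                                          levels = c("a", "b")))
  expect_equal(nrow(km5$table), 1)
})

test_that("multi-group KM summary carries a global log-rank p", {
  set.seed(5)
  t <- c(rexp(30, 0.2), rexp(30, 0.02))
  km <- kmSummary(t, rep(1, 60), rep(c("fast", "slow"), each = 30))
  expect_equal(nrow(km$table), 2)
  expect_lt(km$logrankP, 0.001)
  expect_true(km$table$median[km$table$group == "fast"] <
                km$table$median[km$table$group == "slow"])
})

test_that("cross-tab percentages reproduce printed count ratios", {
  # 53 known samples in the cluster, 49 of them grade III -> 92.5%
  lab <- rep(c("c1", "c2"), c(54, 100))
  ann <- c(rep("G3", 49), rep("G2", 4), "unknown",
           rep(c("G2", "G3"), 50))
  ct <- crosstabProportions(lab, ann)
  expect_equal(ct$counts["c1", "G3"], 49)
  expect_equal(ct$percent["c1", "G3"], 92.5)
  expect_equal(unname(ct$unknown["c1"]), 1)
  # 96/97 -> 99.0 with one-decimal rounding
  lab2 <- rep(c("a", "b"), each = 97)
  ann2 <- c(rep("mut", 96), "wt", rep("wt", 97))
  ct2 <- crosstabProportions(lab2, ann2)
  expect_equal(ct2$percent["a", "mut"], 99.0)
  # 0 of n -> 0.0
  expect_equal(ct2$percent["b", "mut"], 0.0)
  # percentages always recompute from counts
  denom <- rowSums(ct$counts)
  expect_equal(ct$percent, round(100 * ct$counts / denom, 1))
})

test_that("association testing falls back to Fisher for sparse tables", {
  lab <- rep(c("x", "y"), each = 8)
  ann <- c(rep("m", 7), "w", rep("w", 7), "m")
  ct <- crosstabProportions(lab, ann)
  expect_equal(ct$test, "fisher")
  expect_lt(ct$p, 0.05)
  lab2 <- rep(c("x", "y"), each = 100)
  ann2 <- rep(rep(c("m", "w"), c(30, 70)), 2)
  ct2 <- crosstabProportions(lab2, ann2)
  expect_equal(ct2$test, "chi-square")
  expect_gt(ct2$p, 0.9)
})

test_that("treatment-stratified survival skips unusable clusters", {
  clin <- data.frame(sample_id = sprintf("s%02d", 1:30),
                     os_months = rexp(30, 0.1), os_event = 1,
                     standard_therapy = c(rep(c("0", "1"), 10),
                                          rep("unknown", 10)))
  lab <- setNames(rep(c(1, 2), c(20, 10)), clin$sample_id)
  res <- treatmentStratifiedSurvival(clin, lab)
  expect_equal(nrow(res), 2)
  expect_false(is.na(res$p[1]))
  expect_true(is.na(res$p[2]))
  expect_match(res$note[2], "skipped")
  # identical arms -> p = 1
  clin2 <- data.frame(sample_id = sprintf("u%02d", 1:20),
                      os_months = rep(c(2, 5, 9, 14, 30), 4),
                      os_event = rep(c(1, 1, 0, 1, 1), 4),
                      standard_therapy = rep(c("0", "1"), 10))
  res2 <- treatmentStratifiedSurvival(clin2,
                                      setNames(rep(1, 20),
                                               clin2$sample_id))
  expect_equal(res2$p, 1, tolerance = 1e-12)
})

test_that("PCA projection is deterministic and separates planted clusters", {
  coh <- smallCohort(seed = 25, n = 60, nEvents = 20, k = 2,
                     concentration = 100, fractionInformative = 0.6)
  m <- psiValues(coh$psi)
  pr <- pcaProjection(m)
  expect_equal(dim(pr$coords), c(60L, 2L))
  expect_lte(sum(pr$varExplained), 1)
  cl <- coh$truth$clusters[rownames(pr$coords)]
  between <- abs(mean(pr$coords[cl == 1, 1]) -
                   mean(pr$coords[cl == 2, 1]))
  within <- max(sd(pr$coords[cl == 1, 1]), sd(pr$coords[cl == 2, 1]))
  expect_gt(between, within)
  # duplicate samples project identically
  m2 <- cbind(m, dup = m[, 1])
  colnames(m2)[ncol(m2)] <- "dup"
  pr2 <- pcaProjection(m2)
  expect_equal(unname(pr2$coords["dup", ]),
               unname(pr2$coords[colnames(m)[1], ]), tolerance = 1e-9)
  # deterministic sign convention: largest-magnitude loading positive
  pr3 <- pcaProjection(m)
  expect_identical(pr$coords, pr3$coords)
  expect_error(pcaProjection(m[1, , drop = FALSE]), "at least 2 events")
})

test_that("the bundled report is self-consistent", {
  coh <- smallCohort(seed = 27, n = 70, nEvents = 20, k = 2,
                     concentration = 80, fractionInformative = 0.6)
  lab <- coh$truth$clusters
  rep <- clusterReport(coh$psi, coh$clinical, lab,
                       signatureIds = rownames(coh$psi)[1:5])
  expect_equal(nrow(rep$km$table), 2)
  expect_true(all(vapply(rep$crosstabs, function(ct)
    all(ct$percent >= 0 & ct$percent <= 100), logical(1))))
  expect_equal(nrow(rep$treatment), 2)
  expect_equal(dim(rep$pca$coords)[2], 2L)
})
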