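# Two well-separated Gaussian clouds: spread ~1, separation >= 10.
twoClouds <- function(n1 = 20, n2 = 20, f = 5, gap = 20, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n1 * f, 0), n1, f),
        matrix(rnorm(n2 * f, gap), n2, f))
}

test_that("perfectly separable data give a 0/1 block consensus matrix", {
  X <- twoClouds()
  M <- consensusMatrix(X, 2, nResamples = 60, seed = 3)
  expect_true(all(M %in% c(0, 1)))
  expect_true(all(M[1:20, 1:20] == 1))
  expect_true(all(M[1:20, 21:40] == 0))
})

test_that("the PAM inner clusterer agrees with k-means in the separable limit", {
  X <- twoClouds(n1 = 10, n2 = 10, f = 4, gap = 15, seed = 5)
  M <- consensusMatrix(X, 2, nResamples = 30, seed = 2,
                       innerAlgorithm = "pam")
  expect_true(all(M[1:10, 1:10] == 1))
  expect_true(all(M[1:10, 11:20] == 0))
})

test_that("consensus matrices are deterministic given a seed and valid", {
  X <- twoClouds(gap = 2)
  M1 <- consensusMatrix(X, 3, nResamples = 40, seed = 7)
  M2 <- consensusMatrix(X, 3, nResamples = 40, seed = 7)
  expect_identical(M1, M2)
  expect_true(isSymmetric(M1))
  expect_equal(unname(diag(M1)), rep(1, 40))
  expect_true(all(M1 >= 0 & M1 <= 1))
  expect_error(consensusMatrix(X, 1), "k")
  expect_error(consensusMatrix(X[1:5, ], 2, nResamples = 1,
                               itemFrac = 0.5, seed = 1),
               "never co-sampled")
})

test_that("a single Gaussian cloud at k=2 is ambiguous (high PAC)", {
  set.seed(9)
  pacs <- vapply(1:5, function(s) {
    X <- matrix(rnorm(50 * 2), 50, 2)
    M <- consensusMatrix(X, 2, nResamples = 80, seed = s)
    cdfAndPac(M)$pac
  }, numeric(1))
  # far from the separable limit (PAC = 0) on every draw
  expect_true(all(pacs > 0.2))
  expect_gt(mean(pacs), 0.4)
})

test_that("PAC hits its exact endpoints and counts the open window", {
  n <- 10
  # block 0/1 consensus: no ambiguity
  M0 <- matrix(0, n, n); M0[1:5, 1:5] <- 1; M0[6:10, 6:10] <- 1
  expect_identical(cdfAndPac(M0)$pac, 0)
  # everything maximally ambiguous
  M5 <- matrix(0.5, n, n); diag(M5) <- 1
  expect_identical(cdfAndPac(M5)$pac, 1)
  # direct-count oracle: PAC is the fraction of upper-triangle entries
  # inside the ambiguity window (of 0, 0.05, 0.5, 0.95, 1 only 0.5 is)
  x <- c(0.0, 0.05, 0.5, 0.95, 1.0, 0.3)
  Ms <- diag(4)
  Ms[upper.tri(Ms)] <- x
  Ms <- pmax(Ms, t(Ms)); diag(Ms) <- 1
  expect_equal(cdfAndPac(Ms)$pac, mean(x > 0.1 & x <= 0.9))
  expect_equal(cdfAndPac(Ms)$pac, 2 / 6)
  # ... and for a random symmetric matrix
  set.seed(1)
  R <- matrix(runif(64), 8, 8); R <- (R + t(R)) / 2; diag(R) <- 1
  u <- R[upper.tri(R)]
  expect_equal(cdfAndPac(R)$pac, mean(u > 0.1 & u <= 0.9))
})

test_that("null references preserve correlation structure but not clusters", {
  set.seed(4)
  # two independent unit-variance features -> isotropic null
  X <- matrix(rnorm(500 * 2), 500, 2)
  nulls <- simulateNullReferences(X, nNull = 5, seed = 4)
  cc <- cov(nulls[[1]])
  expect_equal(unname(diag(cc)), c(1, 1), tolerance = 0.2)
  expect_lt(abs(cc[1, 2]), 0.15)

  # correlated features: null correlation matrices track the input's
  S <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(rnorm(36), 6, 6)
  draws <- simulateNullReferences(S, nNull = 10, seed = 5)
  rms <- vapply(draws, function(d)
    sqrt(mean((cor(d) - cor(S))^2)), numeric(1))
  expect_true(all(rms < 0.1))
  expect_true(all(vapply(draws, function(d)
    identical(dim(d), dim(S)), logical(1))))

  expect_identical(simulateNullReferences(X, 3, seed = 11),
                   simulateNullReferences(X, 3, seed = 11))
  Xz <- cbind(X, 0)
  expect_warning(simulateNullReferences(Xz, 2, seed = 1), "zero-variance")
})

test_that("RCSI and empirical p follow their defining formulas", {
  r <- rcsiAndPvalue(0.2, c(0.2, 0.2, 0.2))
  expect_equal(r$rcsi, 0)
  # below every null: smallest attainable add-one p
  r2 <- rcsiAndPvalue(0.01, c(0.3, 0.4, 0.5, 0.6))
  expect_equal(r2$empiricalP, 1 / 5)
  # direct formula evaluation
  r3 <- rcsiAndPvalue(0.1, c(0.4, 0.2, 0.05))
  expect_equal(r3$rcsi, log((0.65 / 3) / 0.1))
  expect_equal(r3$empiricalP, 2 / 4)
  r4 <- rcsiAndPvalue(0, c(0.3, 0.2))
  expect_identical(r4$rcsi, Inf)
  expect_equal(r4$empiricalP, 1 / 3)
  expect_error(rcsiAndPvalue(0.5, numeric()), "non-empty")
})

test_that("selectK takes the most stable significant k or declares no structure", {
  st <- data.frame(k = 2:5, pac = c(0.3, 0.1, 0.2, 0.4),
                   rcsi = c(0.5, 1.2, 0.8, 0.1),
                   empiricalP = c(0.2, 0.03, 0.04, 0.5))
  sel <- selectK(st)
  expect_equal(sel$chosenK, 3L)
  st$empiricalP <- rep(0.5, 4)
  expect_equal(selectK(st)$verdict, "no structure")
  expect_true(is.na(selectK(st)$chosenK))
})

test_that("cluster assignment recovers blocks and numbers them by size", {
  n <- 12
  M <- matrix(0, n, n)
  M[1:3, 1:3] <- 1; M[4:8, 4:8] <- 1; M[9:12, 9:12] <- 1
  rownames(M) <- colnames(M) <- paste0("s", 1:n)
  lab <- assignClusters(M, 3)
  expect_equal(length(unique(lab)), 3)
  # blocks intact
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:8])), 1)
  expect_equal(length(unique(lab[9:12])), 1)
  # largest block (5 samples) is cluster 1, then 4, then 3
  expect_equal(unname(lab[4]), 1L)
  expect_equal(unname(lab[9]), 2L)
  expect_equal(unname(lab[1]), 3L)
})

test_that("consensus entries follow a sample permutation", {
  X <- twoClouds(n1 = 10, n2 = 10, gap = 3)
  rownames(X) <- paste0("s", 1:20)
  M <- consensusMatrix(X, 2, nResamples = 50, seed = 2)
  perm <- sample(20)
  Mp <- consensusMatrix(X[perm, ], 2, nResamples = 50, seed = 2)
  # not identical resample draws, but the structure must agree strongly
  expect_equal(dim(Mp), c(20L, 20L))
  expect_equal(Mp[rownames(M), rownames(M)][1:10, 1:10],
               M[1:10, 1:10], tolerance = 0.35)
})

test_that("PAC at k_true does not decrease as within-cluster noise grows", {
  pacs <- vapply(c(120, 30, 8), function(conc) {
    coh <- simulateCohort(simulationConfig(
      nSamples = 60, nEvents = 20, kTrue = 2, concentration = conc,
      fractionInformative = 0.5, nPrognostic = 5, nFactors = 1,
      missingRate = 0, seed = 31))
    M <- consensusMatrix(scale(t(psiValues(coh$psi))), 2,
                         nResamples = 60, seed = 31)
    cdfAndPac(M)$pac
  }, numeric(1))
  expect_true(all(diff(pacs) >= -1e-9))
})

test_that("end-to-end consensus run returns a coherent ConsensusResult", {
  coh <- smallCohort(seed = 13, n = 50, nEvents = 20, k = 2,
                     concentration = 80, fractionInformative = 0.5)
  # nNull >= 20 is needed for the add-one empirical p to go below 0.05
  res <- consensusCluster(coh$psi, kRange = 2:4, nResamples = 50,
                          nNull = 20, seed = 13)
  expect_s4_class(res, "ConsensusResult")
  st <- clusterStats(res)
  expect_equal(st$k, 2:4)
  expect_true(all(st$empiricalP > 0 & st$empiricalP <= 1))
  expect_equal(chosenK(res), 2L)
  lab <- clusterLabels(res)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_gt(ariOracle(lab, coh$truth$clusters[names(lab)]), 0.9)
  # re-cutting at another k through the accessor
  expect_equal(length(unique(clusterLabels(res, 3))), 3)
  # missing PSI is refused at this stage
  cohNA <- smallCohort(seed = 13, n = 30, nEvents = 10, missingRate = 0.1)
  expect_error(consensusCluster(cohNA$psi, kRange = 2:3, seed = 1),
               "missing")
})
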