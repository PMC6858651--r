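## Monte-Carlo consensus clustering with a simulated-null hypothesis test:
## resampled consensus matrices, CDF/PAC stability statistics, PCA-matched
## multivariate-normal null references, RCSI and empirical p per k, and
## selection of the number of clusters.

#' @useDynLib SpliceTypes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Resampled consensus matrix
#'
#' Entry (i, j) is the fraction of resamples in which samples i and j were
#' assigned to the same cluster, among resamples containing both.  Each
#' resample draws \code{floor(itemFrac * n)} samples without replacement
#' and clusters them with the inner algorithm (k-means with \code{nStart}
#' random restarts by default; PAM via the \pkg{cluster} package as an
#' option).
#'
#' @param data Samples-x-features numeric matrix without missing values.
#' @param k Number of clusters (2 <= k < number of samples).
#' @param nResamples Number of resamples (default 100).
#' @param itemFrac Fraction of samples drawn per resample (default 0.8).
#' @param seed Optional integer seed (\code{set.seed} is called when
#'   supplied; otherwise the current RNG stream is used).
#' @param innerAlgorithm \code{"kmeans"} (default) or \code{"pam"}.
#' @param nStart Random restarts for k-means (default 10).
#' @return Symmetric samples-x-samples matrix with unit diagonal, entries
#'   in [0, 1].
#' @export
consensusMatrix <- function(data, k, nResamples = 100, itemFrac = 0.8,
                            seed = NULL,
                            innerAlgorithm = c("kmeans", "pam"),
                            nStart = 10) {
  innerAlgorithm <- match.arg(innerAlgorithm)
  data <- as.matrix(data)
  if (anyNA(data)) stop("data must not contain missing values")
  n <- nrow(data)
  if (k < 2 || k >= n) stop("need 2 <= k < number of samples")
  if (!is.null(seed)) set.seed(seed)
  if (innerAlgorithm == "kmeans") {
    res <- .cppConsensus(data, as.integer(k), as.integer(nResamples),
                         itemFrac, as.integer(nStart), 100L)
    conn <- res$conn; both <- res$both
  } else {
    m <- max(k + 1, floor(itemFrac * n))
    conn <- matrix(0, n, n); both <- matrix(0, n, n)
    for (b in seq_len(nResamples)) {
      idx <- sample(n, m)
      cl <- cluster::pam(data[idx, , drop = FALSE], k,
                         cluster.only = TRUE, pamonce = 5)
      ind <- diag(k)[cl, , drop = FALSE]
      conn[idx, idx] <- conn[idx, idx] + tcrossprod(ind)
      both[idx, idx] <- both[idx, idx] + 1
    }
  }
  off <- both == 0 & !diag(n)
  if (any(off))
    stop("some sample pairs were never co-sampled; increase nResamples")
  M <- conn / pmax(both, 1)
  diag(M) <- 1
  dimnames(M) <- list(rownames(data), rownames(data))
  M
}

#' CDF and PAC of a consensus matrix
#'
#' The empirical cumulative distribution of the upper-triangle consensus
#' entries, and the proportion of ambiguous clustering
#' \eqn{PAC = F(u_2) - F(u_1)} for the window \code{(0.1, 0.9)} by
#' default.  PAC is 0 when every pair is always or never co-clustered and
#' 1 when all entries sit mid-window.
#'
#' @param consensus A consensus matrix from [consensusMatrix()].
#' @param window Lower/upper bounds of the ambiguity window.
#' @return List with \code{cdf} (a \code{data.frame} of the ECDF evaluated
#'   on a 0..1 grid) and \code{pac}.
#' @export
cdfAndPac <- function(consensus, window = c(0.1, 0.9)) {
  x <- consensus[upper.tri(consensus)]
  F <- stats::ecdf(x)
  grid <- seq(0, 1, by = 0.01)
  list(cdf = data.frame(u = grid, F = F(grid)),
       pac = as.numeric(F(window[2L]) - F(window[1L])))
}

#' Simulate null reference datasets
#'
#' Draws multivariate-normal datasets whose feature covariance
#' eigenstructure matches the input (via the input's principal-component
#' decomposition) but with no cluster structure: the reference
#' distribution for the PAC hypothesis test.  Zero-variance features are
#' dropped with a warning.
#'
#' @param data Samples-x-features matrix (>= 2 features).
#' @param nNull Number of null datasets (default 25).
#' @param seed Optional integer seed.
#' @return List of \code{nNull} matrices, same shape as \code{data} (minus
#'   any dropped features).
#' @export
simulateNullReferences <- function(data, nNull = 25, seed = NULL) {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop("need at least 2 features")
  v <- apply(data, 2L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) dropped")
    data <- data[, v > 0, drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  mu <- colMeans(data)
  sv <- svd(scale(data, center = TRUE, scale = FALSE))
  r <- sum(sv$d > 1e-10)
  load <- sv$v[, seq_len(r), drop = FALSE] *
    rep(sv$d[seq_len(r)] / sqrt(n - 1), each = ncol(data))
  lapply(seq_len(nNull), function(i) {
    Z <- matrix(stats::rnorm(n * r), n, r)
    sweep(Z %*% t(load), 2L, mu, "+")
  })
}

#' RCSI and empirical p-value
#'
#' \eqn{RCSI = \ln(\overline{PAC}_{null} / PAC_{real})} (larger = more
#' real structure relative to the matched null), and the add-one empirical
#' p-value \eqn{(1 + \#\{PAC_{null} \le PAC_{real}\}) / (1 + n_{null})},
#' which is never zero.
#'
#' @param realPac Observed PAC.
#' @param nullPacs Non-empty numeric vector of null PACs (all > 0).
#' @return List with \code{rcsi} (\code{Inf} when \code{realPac} is 0) and
#'   \code{empiricalP}.
#' @export
rcsiAndPvalue <- function(realPac, nullPacs) {
  if (length(nullPacs) == 0L) stop("nullPacs must be non-empty")
  empiricalP <- (1 + sum(nullPacs <= realPac)) / (1 + length(nullPacs))
  rcsi <- if (realPac == 0) Inf else log(mean(nullPacs) / realPac)
  list(rcsi = rcsi, empiricalP = empiricalP)
}

#' Select the number of clusters from per-k stability statistics
#'
#' Default rule: among k with empirical p < \code{alpha}, choose the one
#' with maximal RCSI; when no k is significant the verdict is
#' \code{"no structure"}.  The full per-k table is always returned so a
#' caller can deliberately override the automatic choice (for instance to
#' prefer a larger significant k for finer granularity).
#'
#' @param stats \code{data.frame} with columns \code{k}, \code{pac},
#'   \code{rcsi}, \code{empiricalP} covering the whole candidate range.
#' @param alpha Significance level on the empirical p (default 0.05).
#' @return List with \code{chosenK} (integer, \code{NA} if none),
#'   \code{verdict} (\code{"structure"}/\code{"no structure"}) and the
#'   \code{stats} table.
#' @export
selectK <- function(stats, alpha = 0.05) {
  sig <- which(stats$empiricalP < alpha)
  if (length(sig) == 0L)
    return(list(chosenK = NA_integer_, verdict = "no structure",
                stats = stats))
  best <- sig[which.max(stats$rcsi[sig])]
  list(chosenK = as.integer(stats$k[best]), verdict = "structure",
       stats = stats)
}

#' Final cluster assignment from a consensus matrix
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity
#' \code{1 - consensus}, cut at k clusters; labels are renumbered by
#' decreasing cluster size (largest cluster = 1, ties broken by first
#' occurrence).
#'
#' @param consensus A consensus matrix.
#' @param k Number of clusters.
#' @return Integer labels in \code{1..k}, named by sample.
#' @export
assignClusters <- function(consensus, k) {
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  first <- vapply(names(sizes), function(g) which(raw == g)[1L], 1L)
  ord <- order(-as.integer(sizes), first)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- relabel[as.character(raw)]
  stats::setNames(as.integer(out), names(raw))
}

#' Monte-Carlo consensus clustering over a range of k
#'
#' Runs [consensusMatrix()] for every k in \code{kRange} on the real data
#' and on \code{nNull} PCA-matched null references (shared across k),
#' computes PAC, RCSI and the empirical p per k, selects k by
#' [selectK()], and assigns final labels at the chosen k via
#' [assignClusters()].
#'
#' @param data Samples-x-features matrix without missing values, or a
#'   \linkS4class{PsiExperiment} (samples = columns; an optional
#'   \code{events} argument restricts to a subset of event ids, e.g. the
#'   prognostic set).
#' @param kRange Candidate cluster numbers (default \code{2:8}).
#' @param nResamples Resamples per consensus matrix (default 100).
#' @param nNull Null reference datasets (default 25).
#' @param itemFrac Subsample fraction (default 0.8).
#' @param pacWindow PAC ambiguity window (default \code{c(0.1, 0.9)}).
#' @param scaleFeatures Standardize each feature to zero mean and unit
#'   variance before clustering (default \code{TRUE}; zero-variance
#'   features are dropped).
#' @param seed Optional integer seed governing the whole run.
#' @param events Optional character vector of event ids (PsiExperiment
#'   input only).
#' @param innerAlgorithm Passed to [consensusMatrix()].
#' @param alpha Significance level for [selectK()] (default 0.05).
#' @return A \linkS4class{ConsensusResult}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40 * 5, 0), 40), matrix(rnorm(40 * 5, 4), 40))
#' res <- consensusCluster(x, kRange = 2:4, nResamples = 25, nNull = 8,
#'                         seed = 1)
#' chosenK(res)
#' @export
consensusCluster <- function(data, kRange = 2:8, nResamples = 100,
                             nNull = 25, itemFrac = 0.8,
                             pacWindow = c(0.1, 0.9),
                             scaleFeatures = TRUE, seed = NULL,
                             events = NULL,
                             innerAlgorithm = c("kmeans", "pam"),
                             alpha = 0.05) {
  innerAlgorithm <- match.arg(innerAlgorithm)
  if (is(data, "PsiExperiment")) {
    m <- psiValues(data)
    if (!is.null(events)) m <- m[events, , drop = FALSE]
    if (anyNA(m))
      stop("PSI contains missing values; cluster only on events that ",
           "pass the screen's completeness filter")
    data <- t(m)
  }
  data <- as.matrix(data)
  if (scaleFeatures) {
    v <- apply(data, 2L, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance feature(s) dropped")
      data <- data[, v > 0, drop = FALSE]
    }
    data <- scale(data)
  }
  kRange <- as.integer(sort(kRange))
  if (!is.null(seed)) set.seed(seed)

  nulls <- simulateNullReferences(data, nNull = nNull)
  consensus <- list()
  statsTab <- data.frame(k = kRange, pac = NA_real_,
                         meanNullPac = NA_real_, rcsi = NA_real_,
                         empiricalP = NA_real_)
  nullPac <- list()
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    M <- consensusMatrix(data, k, nResamples = nResamples,
                         itemFrac = itemFrac,
                         innerAlgorithm = innerAlgorithm)
    consensus[[as.character(k)]] <- M
    pac <- cdfAndPac(M, window = pacWindow)$pac
    np <- vapply(nulls, function(nd)
      cdfAndPac(consensusMatrix(nd, k, nResamples = nResamples,
                                itemFrac = itemFrac,
                                innerAlgorithm = innerAlgorithm),
                window = pacWindow)$pac, numeric(1L))
    ## A PAC of exactly 0 (every pair always or never co-clustered) makes
    ## the RCSI ratio degenerate, and several k can be perfectly stable at
    ## once.  Clamping PAC at the resolution of the resampling scheme
    ## before taking the log-ratio ranks such k by how unstable their
    ## matched null is, which favours the finest perfectly-stable
    ## partition.  The stats table keeps the unclamped PAC.
    clamp <- 1 / (nResamples * nrow(data))
    rp <- rcsiAndPvalue(pac, np)
    nullPac[[as.character(k)]] <- np
    statsTab$pac[i] <- pac
    statsTab$meanNullPac[i] <- mean(np)
    statsTab$rcsi[i] <- log(mean(pmax(np, clamp)) / max(pac, clamp))
    statsTab$empiricalP[i] <- rp$empiricalP
  }
  sel <- selectK(statsTab, alpha = alpha)
  labels <- if (is.na(sel$chosenK)) integer(0)
            else assignClusters(consensus[[as.character(sel$chosenK)]],
                                sel$chosenK)
  new("ConsensusResult", kRange = kRange, consensus = consensus,
      stats = statsTab, nullPac = nullPac,
      chosenK = if (is.na(sel$chosenK)) NA_integer_ else sel$chosenK,
      labels = labels)
}
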