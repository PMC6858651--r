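// Resampled-consensus inner loop: repeated subsampling of items plus
// k-means (Lloyd, multiple random restarts) on each subsample, with
// co-clustering and co-sampling counts accumulated across resamples.
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Lloyd k-means on X (m x f) with given initial center rows; returns WSS,
// fills 'assign'. Distances go through BLAS (X * C^T). Empty clusters are
// re-seeded with the worst-fitted point.
static double lloyd(const arma::mat& X, const arma::vec& xnorm, int k,
                    int maxIter, arma::uvec& assign,
                    const arma::uvec& initIdx) {
  const arma::uword m = X.n_rows;
  arma::mat C = X.rows(initIdx);  // k x f
  arma::uvec prev(m);
  prev.fill(m + 1);
  arma::vec bestD(m, arma::fill::zeros);
  for (int it = 0; it < maxIter; ++it) {
    arma::mat D = X * C.t();                       // m x k
    D.each_row() %= arma::rowvec(k, arma::fill::value(-2.0));
    D.each_row() += arma::sum(arma::square(C), 1).t();
    assign = arma::index_min(D, 1);
    bestD = arma::min(D, 1) + xnorm;
    // re-seed empty clusters with the point farthest from its center
    for (int j = 0; j < k; ++j) {
      if (!arma::any(assign == (unsigned)j)) {
        arma::uword worst = bestD.index_max();
        assign(worst) = j;
        bestD(worst) = 0.0;
      }
    }
    if (arma::all(assign == prev)) break;
    prev = assign;
    C.zeros();
    arma::vec cnt(k, arma::fill::zeros);
    for (arma::uword i = 0; i < m; ++i) {
      C.row(assign(i)) += X.row(i);
      cnt(assign(i)) += 1.0;
    }
    for (int j = 0; j < k; ++j)
      if (cnt(j) > 0) C.row(j) /= cnt(j);
  }
  return arma::accu(bestD);
}

// [[Rcpp::export(name = ".cppConsensus")]]
List cppConsensus(const arma::mat& X, int k, int nResamples,
                  double itemFrac, int nStart, int maxIter) {
  const int n = X.n_rows;
  const int m = std::max(k + 1, (int)std::floor(itemFrac * n));
  if (m > n) stop("subsample larger than the number of items");
  arma::mat conn(n, n, arma::fill::zeros);
  arma::mat both(n, n, arma::fill::zeros);
  IntegerVector all = seq_len(n);
  for (int b = 0; b < nResamples; ++b) {
    IntegerVector idx = sample(all, m, false);
    arma::uvec uidx(m);
    for (int i = 0; i < m; ++i) uidx(i) = idx[i] - 1;
    arma::mat S = X.rows(uidx);
    arma::vec snorm = arma::sum(arma::square(S), 1);
    arma::uvec bestAssign, assign;
    double bestW = std::numeric_limits<double>::max();
    IntegerVector rows = seq_len(m);
    for (int s = 0; s < nStart; ++s) {
      IntegerVector init = sample(rows, k, false);
      arma::uvec uinit(k);
      for (int j = 0; j < k; ++j) uinit(j) = init[j] - 1;
      const double w = lloyd(S, snorm, k, maxIter, assign, uinit);
      if (w < bestW) { bestW = w; bestAssign = assign; }
    }
    for (int i = 0; i < m; ++i) {
      const arma::uword gi = uidx(i);
      for (int j = i; j < m; ++j) {
        const arma::uword gj = uidx(j);
        both(gi, gj) += 1.0;
        both(gj, gi) = both(gi, gj);
        if (bestAssign(i) == bestAssign(j)) {
          conn(gi, gj) += 1.0;
          conn(gj, gi) = conn(gi, gj);
        }
      }
    }
  }
  return List::create(_["conn"] = conn, _["both"] = both);
}
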