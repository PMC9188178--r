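// Successive projections: build one low-collinearity variable chain by
// repeatedly deflating all columns against the span of the chosen ones.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// X: (already centered) spectra matrix, start: 0-based column, k: chain
// length. Ties in projected norm break toward the lowest column index.
// Truncates (with truncated = true) when the best remaining projected norm
// falls below tol * max initial column norm (rank exhausted).
// [[Rcpp::export]]
List cpp_spa_chain(const arma::mat& X, int start, int k, double tol = 1e-9) {
  const int p = X.n_cols;
  arma::mat W = X;  // working copy, deflated in place
  std::vector<int> chain;
  std::vector<bool> used(p, false);
  const arma::vec cn = arma::sqrt(arma::sum(arma::square(X), 0).t());
  const double scale = cn.max();
  bool truncated = false;

  int cur = start;
  for (int step = 0; step < k; ++step) {
    chain.push_back(cur);
    used[cur] = true;
    double nrm = arma::norm(W.col(cur));
    if (nrm < tol * std::max(scale, 1.0)) { truncated = true; break; }
    arma::vec u = W.col(cur) / nrm;
    W -= u * (u.t() * W);  // project all columns off the chosen direction

    if (step == k - 1) break;
    // next: maximal projected norm among unused columns, first index wins
    arma::rowvec nn = arma::sqrt(arma::sum(arma::square(W), 0));
    int best = -1;
    double bestn = tol * std::max(scale, 1.0);
    for (int j = 0; j < p; ++j)
      if (!used[j] && nn[j] > bestn) { bestn = nn[j]; best = j; }
    if (best < 0) { truncated = true; break; }
    cur = best;
  }
  return List::create(_["chain"] = wrap(chain), _["truncated"] = truncated);
}
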