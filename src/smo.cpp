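// SMO solver for binary C-SVC. Operates on a precomputed kernel matrix so
// that RBF grid search can reuse one squared-distance matrix per dataset
// (K_g = exp(-g * D) is an elementwise transform).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Pairwise squared Euclidean distances between rows of A and rows of B.
// [[Rcpp::export]]
arma::mat cpp_sqdist(const arma::mat& A, const arma::mat& B) {
  arma::colvec an = arma::sum(arma::square(A), 1);
  arma::colvec bn = arma::sum(arma::square(B), 1);
  arma::mat D = -2.0 * (A * B.t());
  D.each_col() += an;
  D.each_row() += bn.t();
  D.elem(arma::find(D < 0)).zeros();  // numerical floor
  return D;
}

// Maximal-violating-pair SMO.
// Minimize 0.5 a'Qa - e'a, Q_ij = y_i y_j K_ij, s.t. 0 <= a <= C, y'a = 0.
// Returns alpha, intercept b (decision f(x) = sum_i alpha_i y_i K(x_i,x) + b),
// iteration count, and a convergence flag.
// [[Rcpp::export]]
List cpp_smo_train(const arma::mat& K, const arma::ivec& y, double C,
                   double eps = 1e-3, int max_iter = 0) {
  const int n = K.n_rows;
  if (max_iter <= 0) max_iter = std::max(20000, 200 * n);
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n);
  G.fill(-1.0);  // gradient of the dual objective at alpha = 0

  int iter = 0;
  bool converged = false;
  double Gmax = 0, Gmin = 0;
  while (iter < max_iter) {
    // working-set selection: i in I_up maximizing -y G, j in I_low minimizing
    int i = -1, j = -1;
    Gmax = -arma::datum::inf;
    Gmin = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) { converged = true; break; }

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double t_step = (Gmax - Gmin) / quad;  // = (-y_i G_i + y_j G_j)/quad > 0

    // box constraints along direction (y_i e_i - y_j e_j)
    double ti = (y[i] == 1) ? (C - alpha[i]) : alpha[i];
    double tj = (y[j] == 1) ? alpha[j] : (C - alpha[j]);
    t_step = std::min(t_step, std::min(ti, tj));

    alpha[i] += y[i] * t_step;
    alpha[j] -= y[j] * t_step;
    for (int t = 0; t < n; ++t)
      G[t] += t_step * y[t] * (K(t, i) - K(t, j));
    ++iter;
  }

  // intercept: average of (y_i - S_i) over free SVs, else midpoint of bounds
  double b = 0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  b = (nfree > 0) ? b / nfree : 0.5 * (Gmax + Gmin);

  return List::create(_["alpha"] = alpha, _["b"] = b,
                      _["iterations"] = iter, _["converged"] = converged);
}
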