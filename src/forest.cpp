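// Bagged CART (gini) forest for binary classification. Uses R's RNG so
// set.seed() on the R side makes training reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> pred;      // leaf: fraction of class 1
};

int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)std::floor(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// gini impurity decrease scan on one feature; returns best threshold or NA
bool best_split_on_feature(const NumericMatrix& X, const IntegerVector& y,
                           const std::vector<int>& idx, int f,
                           double& best_gain, double& best_thr,
                           double parent_imp) {
  const int m = idx.size();
  std::vector<std::pair<double, int>> v(m);
  for (int i = 0; i < m; ++i) v[i] = {X(idx[i], f), y[idx[i]]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;

  int n1_tot = 0;
  for (int i = 0; i < m; ++i) n1_tot += v[i].second;
  int nl = 0, n1l = 0;
  bool found = false;
  for (int i = 0; i < m - 1; ++i) {
    ++nl;
    n1l += v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    int nr = m - nl, n1r = n1_tot - n1l;
    double pl = (double)n1l / nl, pr = (double)n1r / nr;
    double imp = (nl * 2.0 * pl * (1 - pl) + nr * 2.0 * pr * (1 - pr)) / m;
    double gain = parent_imp - imp;
    if (gain > best_gain + 1e-15) {
      best_gain = gain;
      best_thr = 0.5 * (v[i].first + v[i + 1].first);
      found = true;
    }
  }
  return found;
}

void grow(Tree& tr, const NumericMatrix& X, const IntegerVector& y,
          std::vector<int>& idx, int mtry, int min_node, int depth,
          int max_depth) {
  const int node = tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  const int m = idx.size();
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  double p1 = (double)n1 / m;
  tr.pred.push_back(p1);
  if (m < 2 * min_node || n1 == 0 || n1 == m ||
      (max_depth > 0 && depth >= max_depth))
    return;

  const int p = X.ncol();
  double parent_imp = 2.0 * p1 * (1 - p1);
  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  double best_gain = 0, best_thr = 0;
  int best_f = -1;
  for (int t = 0; t < mtry; ++t) {
    int r = t + runif_int(p - t);
    std::swap(feats[t], feats[r]);
    double thr;
    double g = best_gain;
    if (best_split_on_feature(X, y, idx, feats[t], g, thr, parent_imp)) {
      best_gain = g;
      best_thr = thr;
      best_f = feats[t];
    }
  }
  if (best_f < 0) return;

  std::vector<int> li, ri;
  for (int i : idx)
    (X(i, best_f) <= best_thr ? li : ri).push_back(i);
  if ((int)li.size() < min_node || (int)ri.size() < min_node) return;

  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  { std::vector<int>().swap(idx); }  // free before recursing
  tr.left[node] = tr.feature.size();
  grow(tr, X, y, li, mtry, min_node, depth + 1, max_depth);
  tr.right[node] = tr.feature.size();
  grow(tr, X, y, ri, mtry, min_node, depth + 1, max_depth);
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_train(const NumericMatrix& X, const IntegerVector& y,
                  int num_trees, int mtry, int min_node, int max_depth) {
  const int n = X.nrow();
  List forest(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n);  // bootstrap
    Tree tr;
    grow(tr, X, y, idx, mtry, min_node, 0, max_depth);
    forest[t] = List::create(
        _["feature"] = wrap(tr.feature), _["threshold"] = wrap(tr.threshold),
        _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
        _["pred"] = wrap(tr.pred));
  }
  return forest;
}

// Returns the fraction of trees voting class 1 for each row.
// [[Rcpp::export]]
NumericVector cpp_rf_predict(const List& forest, const NumericMatrix& X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += (pred[node] >= 0.5) ? 1.0 : 0.0;
    }
  }
  return out / (double)T;
}
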