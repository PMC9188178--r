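// Connected-component labeling for binary seed masks.
#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

// Labels foreground (true) pixels of `mask` with 1..n_components in raster
// discovery order; background stays 0. connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nd = (connectivity == 4) ? 4 : 8;

  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push({r, c});
      while (!q.empty()) {
        auto [cr, cc] = q.front();
        q.pop();
        for (int d = 0; d < nd; ++d) {
          int rr = cr + dr[d], ccn = cc + dc[d];
          if (rr < 0 || rr >= nr || ccn < 0 || ccn >= nc) continue;
          if (mask(rr, ccn) && lab(rr, ccn) == 0) {
            lab(rr, ccn) = next;
            q.push({rr, ccn});
          }
        }
      }
    }
  }
  return lab;
}
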