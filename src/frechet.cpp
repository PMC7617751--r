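#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between two 2-D polylines (rows = points),
// by the standard O(nm) dynamic program on the coupling table.
// [[Rcpp::export]]
double frechet_dist_cpp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      double best;
      if (i == 0 && j == 0) best = d;
      else if (i == 0) best = std::max(cur[j - 1], d);
      else if (j == 0) best = std::max(prev[0], d);
      else best = std::max(std::min(std::min(prev[j], prev[j - 1]), cur[j - 1]), d);
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
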