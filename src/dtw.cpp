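#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classic dynamic-programming DTW with Euclidean local cost and steps
// {(1,0),(0,1),(1,1)}; no band constraint. Rows of a and b are time points.
// [[Rcpp::export]]
double dtw_dp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      const double c = std::sqrt(s);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else if (i == 0) {
        best = cur[j - 1];
      } else if (j == 0) {
        best = prev[0];
      } else {
        best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
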