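#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sum of the k largest entries of each column of x. Hot path of the
// per-replicate top-fraction statistic: called once per window with
// x = squared MVN draws (m SNPs x nsim replicates).
// [[Rcpp::export]]
NumericVector top_k_col_sums(NumericMatrix x, int k) {
  const int m = x.nrow(), n = x.ncol();
  if (k < 1 || k > m) stop("k must lie in [1, nrow(x)]");
  NumericVector out(n);
  std::vector<double> col(m);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) col[i] = x(i, j);
    std::nth_element(col.begin(), col.begin() + (k - 1), col.end(),
                     std::greater<double>());
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += col[i];
    out[j] = s;
  }
  return out;
}
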