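#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Column-wise average-tie ranks, centered and scaled to unit Euclidean
// norm, so that crossprod of two such matrices is the Spearman correlation
// of their columns. A constant column gets all-NaN (caller must check).
// [[Rcpp::export]]
NumericMatrix col_rank_standardize_cpp(NumericMatrix m) {
  const int n = m.nrow(), k = m.ncol();
  NumericMatrix out(n, k);
  std::vector<int> ord(n);
  std::vector<double> r(n);
  for (int j = 0; j < k; ++j) {
    const double* col = &m(0, j);
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < n) {
      int i2 = i;
      while (i2 + 1 < n && col[ord[i2 + 1]] == col[ord[i]]) ++i2;
      const double avg = (i + i2) / 2.0 + 1.0;   // average 1-based rank
      for (int t = i; t <= i2; ++t) r[ord[t]] = avg;
      i = i2 + 1;
    }
    const double mu = (n + 1) / 2.0;
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      r[t] -= mu;
      ss += r[t] * r[t];
    }
    const double nrm = std::sqrt(ss);
    for (int t = 0; t < n; ++t) {
      out(t, j) = nrm > 0 ? r[t] / nrm : R_NaN;
    }
  }
  return out;
}
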