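#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Correlation-distance RDM vectors for all sliding windows of one
// searchlight patch.
//
// arr: (n_cond x n_vert_total x n_time) array (column-major) of one
//      subject's source values; patch: 1-based vertex indices of the
//      searchlight patch; starts0: 0-based first-sample index of each
//      window; window: samples per window.
//
// Returns a (n_cond*(n_cond-1)/2) x n_windows matrix; column w holds the
// row-major upper triangle of 1 - r for window w. Uses prefix sums of the
// per-sample condition cross-products, so the cost is O(T * V * n^2 / 2)
// per patch instead of O(W * window * V * n^2). Zero-variance conditions
// yield NaN entries; callers must check.
// [[Rcpp::export]]
NumericMatrix window_rdm_cpp(NumericVector arr, int n_cond, int n_vert_total,
                             int n_time, IntegerVector patch,
                             IntegerVector starts0, int window) {
  const int n = n_cond, P = patch.size(), T = n_time, W = starts0.size();
  const int Vtot = n_vert_total;
  const int np = n * (n + 1) / 2;           // packed symmetric incl. diagonal
  const int p = n * (n - 1) / 2;
  NumericMatrix out(p, W);

  // prefix sums over time of cross-products and of per-condition sums
  std::vector<double> cross((T + 1) * np, 0.0);
  std::vector<double> sums((T + 1) * n, 0.0);
  const double* x = arr.begin();
  for (int t = 0; t < T; ++t) {
    double* cr = &cross[(t + 1) * np];
    double* sm = &sums[(t + 1) * n];
    const double* cr0 = &cross[t * np];
    const double* sm0 = &sums[t * n];
    for (int k = 0; k < np; ++k) cr[k] = cr0[k];
    for (int c = 0; c < n; ++c) sm[c] = sm0[c];
    for (int v = 0; v < P; ++v) {
      const double* col =
          x + (std::size_t)n * ((patch[v] - 1) + (std::size_t)Vtot * t);
      int k = 0;
      for (int i = 0; i < n; ++i) {
        const double xi = col[i];
        sm[i] += xi;
        for (int j = i; j < n; ++j) cr[k++] += xi * col[j];
      }
    }
  }

  const double d = (double)P * window;
  std::vector<double> g(np), mu(n), nrm(n);
  for (int w = 0; w < W; ++w) {
    const int t0 = starts0[w], t1 = t0 + window;
    const double* cA = &cross[t1 * np];
    const double* cB = &cross[t0 * np];
    const double* sA = &sums[t1 * n];
    const double* sB = &sums[t0 * n];
    for (int k = 0; k < np; ++k) g[k] = cA[k] - cB[k];
    for (int c = 0; c < n; ++c) mu[c] = (sA[c] - sB[c]) / d;
    int k = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        g[k] -= d * mu[i] * mu[j];       // centered cross-product
        ++k;
      }
    }
    k = 0;
    for (int i = 0; i < n; ++i) {
      nrm[i] = std::sqrt(g[k]);          // diagonal entry first in row i
      k += n - i;
    }
    int kk = 0, o = 0;
    for (int i = 0; i < n; ++i) {
      ++kk;                              // skip diagonal
      for (int j = i + 1; j < n; ++j) {
        out(o++, w) = 1.0 - g[kk++] / (nrm[i] * nrm[j]);
      }
    }
  }
  return out;
}
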