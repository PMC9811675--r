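#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement on an arbitrary graph.
//
// For node values t_v, computes sum over thresholds h = i*delta_h (i >= 1,
// h <= t_v) of h^2 * e_v(h), where e_v(h) is the size of the connected
// component containing v in the subgraph of nodes with value >= h. Thresholds
// are processed in descending order with an incremental union-find, so the
// total cost is O(n_thresholds * n_active + m alpha(n)). Nodes with value
// below the first threshold (including all non-positive values) get 0.
//
// edges: two-column matrix of 1-based undirected edges.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerMatrix edges,
                       double delta_h) {
  const int n = values.size();
  const int m = edges.nrow();
  NumericVector out(n);
  if (delta_h <= 0) stop("delta_h must be positive");
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (values[i] > vmax) vmax = values[i];
  }
  if (vmax < delta_h) return out;
  int imax = 1;
  while ((imax + 1) * delta_h <= vmax) ++imax;

  std::vector<int> nord(n);
  std::iota(nord.begin(), nord.end(), 0);
  std::sort(nord.begin(), nord.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<double> elev(m);
  std::vector<int> eord(m);
  for (int e = 0; e < m; ++e) {
    elev[e] = std::min(values[edges(e, 0) - 1], values[edges(e, 1) - 1]);
    eord[e] = e;
  }
  std::sort(eord.begin(), eord.end(),
            [&](int a, int b) { return elev[a] > elev[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::iota(parent.begin(), parent.end(), 0);
  int ni = 0, ei = 0;
  for (int i = imax; i >= 1; --i) {
    const double h = i * delta_h;
    while (ni < n && values[nord[ni]] >= h) {
      csize[nord[ni]] = 1;
      ++ni;
    }
    while (ei < m && elev[eord[ei]] >= h) {
      int a = find_root(parent, edges(eord[ei], 0) - 1);
      int b = find_root(parent, edges(eord[ei], 1) - 1);
      if (a != b) {
        if (csize[a] < csize[b]) std::swap(a, b);
        parent[b] = a;
        csize[a] += csize[b];
      }
      ++ei;
    }
    const double h2 = h * h;
    for (int j = 0; j < ni; ++j) {
      const int v = nord[j];
      out[v] += h2 * csize[find_root(parent, v)];
    }
  }
  return out;
}
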