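#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement of a nonnegative statistic map laid out
// on an arbitrary undirected graph.
//
// values: per-node statistic (only values > 0 are enhanced)
// edges:  m x 2 matrix of 0-based node indices
// E, H:   extent and height exponents
// dh:     threshold step; thresholds are h = dh, 2*dh, ... up to max(values)
//
// score(p) = sum_h extent(cluster_h(p))^E * h^H * dh over thresholds h <= v_p
// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector values, IntegerMatrix edges,
                               double E, double H, double dh) {
  const int n = values.size();
  const int m = edges.nrow();
  NumericVector score(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) if (values[i] > vmax) vmax = values[i];
  if (vmax <= 0.0 || dh <= 0.0) return score;

  std::vector<int> parent(n), csize(n);
  const int nsteps = (int)std::floor(vmax / dh + 1e-12);
  for (int k = 1; k <= nsteps; ++k) {
    const double h = k * dh;
    for (int i = 0; i < n; ++i) { parent[i] = i; csize[i] = 1; }
    for (int e = 0; e < m; ++e) {
      const int a = edges(e, 0), b = edges(e, 1);
      if (values[a] >= h && values[b] >= h) {
        int ra = uf_find(parent, a), rb = uf_find(parent, b);
        if (ra != rb) { parent[rb] = ra; csize[ra] += csize[rb]; }
      }
    }
    const double hH_dh = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i) {
      if (values[i] >= h) {
        const int r = uf_find(parent, i);
        score[i] += std::pow((double)csize[r], E) * hH_dh;
      }
    }
  }
  return score;
}
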