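// Threshold-free cluster enhancement for 1-D timecourses and 2-D
// train x test grids (4-neighbour connectivity). Non-negative input maps
// only; the R wrapper handles the signed recombination.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// union-find
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}
static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra] = rb;
}

// TFCE(p) = sum over heights h = dh, 2dh, ... <= v(p) of e(p,h)^E * h^H * dh
// where e(p,h) is the size of the suprathreshold connected component
// containing p at height h.
// [[Rcpp::export]]
NumericVector tfce_nonneg_cpp(NumericVector values, int nrow, int ncol,
                              double e_power, double h_power, double dh) {
  const int n = values.size();
  NumericVector out(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) vmax = std::max(vmax, values[i]);
  if (vmax <= 0.0 || dh <= 0.0) return out;

  std::vector<int> parent(n);
  std::vector<int> csize(n);
  const int n_steps = (int)std::floor(vmax / dh + 1e-9);
  for (int step = 1; step <= n_steps; ++step) {
    const double h = step * dh;
    // label suprathreshold cells
    for (int i = 0; i < n; ++i) parent[i] = i;
    std::vector<bool> up(n);
    for (int i = 0; i < n; ++i) up[i] = values[i] >= h;
    if (ncol == 1 || nrow == 1) {
      for (int i = 1; i < n; ++i)
        if (up[i] && up[i - 1]) uf_union(parent, i, i - 1);
    } else {
      for (int c = 0; c < ncol; ++c) {
        for (int r = 0; r < nrow; ++r) {
          int i = c * nrow + r;
          if (!up[i]) continue;
          if (r + 1 < nrow && up[i + 1]) uf_union(parent, i, i + 1);
          if (c + 1 < ncol && up[i + nrow]) uf_union(parent, i, i + nrow);
        }
      }
    }
    std::fill(csize.begin(), csize.end(), 0);
    for (int i = 0; i < n; ++i)
      if (up[i]) csize[uf_find(parent, i)]++;
    const double hh = std::pow(h, h_power) * dh;
    for (int i = 0; i < n; ++i) {
      if (up[i]) out[i] += std::pow((double)csize[uf_find(parent, i)], e_power) * hh;
    }
  }
  return out;
}

// 4-connected component labels of a logical map (1-based labels, 0 =
// background); used for cluster extraction from significance masks.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int nrow, int ncol) {
  const int n = mask.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  if (ncol == 1 || nrow == 1) {
    for (int i = 1; i < n; ++i)
      if (mask[i] && mask[i - 1]) uf_union(parent, i, i - 1);
  } else {
    for (int c = 0; c < ncol; ++c) {
      for (int r = 0; r < nrow; ++r) {
        int i = c * nrow + r;
        if (!mask[i]) continue;
        if (r + 1 < nrow && mask[i + 1]) uf_union(parent, i, i + 1);
        if (c + 1 < ncol && mask[i + nrow]) uf_union(parent, i, i + nrow);
      }
    }
  }
  IntegerVector labels(n, 0);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++next;
    labels[i] = remap[r];
  }
  return labels;
}
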