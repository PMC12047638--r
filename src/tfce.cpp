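#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cmath>

using namespace Rcpp;

// Union-find with path halving and union by size.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement on an arbitrary voxel adjacency graph.
//
// values: statistic per in-mask voxel (negative values contribute nothing).
// adj_ptr / adj_idx: CSR adjacency over in-mask voxels (0-based).
// h_exp / e_exp: height and extent exponents (defaults 2 and 0.5).
// n_steps: number of integration steps; dh <= 0 selects max(values)/n_steps.
//
// Staircase approximation of the TFCE integral: for each threshold
// h = k * dh (k = 1..n_steps) every suprathreshold voxel accumulates
// e(h)^E * h^H * dh, where e(h) is the size of its connected suprathreshold
// component. Thresholds are processed in descending order so components only
// grow, allowing one incremental union-find pass.
// [[Rcpp::export(name = ".tfce_graph")]]
NumericVector tfce_graph(NumericVector values, IntegerVector adj_ptr,
                         IntegerVector adj_idx, double h_exp, double e_exp,
                         int n_steps, double dh) {
  const int v = values.size();
  NumericVector out(v);
  if (v == 0) return out;

  double vmax = 0.0;
  for (int i = 0; i < v; ++i) {
    if (values[i] > vmax) vmax = values[i];
  }
  if (vmax <= 0.0) return out;
  if (dh <= 0.0) dh = vmax / n_steps;
  int steps = (int)std::ceil(vmax / dh - 1e-12);

  // voxels sorted by value, descending
  std::vector<int> order(v);
  std::iota(order.begin(), order.end(), 0);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(v), csize(v, 0);
  std::vector<char> active(v, 0);
  for (int i = 0; i < v; ++i) parent[i] = i;

  std::vector<int> active_list;
  active_list.reserve(v);

  int next = 0;  // next voxel in descending order not yet activated
  for (int k = steps; k >= 1; --k) {
    const double h = k * dh;
    while (next < v && values[order[next]] >= h) {
      const int i = order[next];
      active[i] = 1;
      csize[i] = 1;
      active_list.push_back(i);
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
        const int j = adj_idx[e];
        if (!active[j]) continue;
        const int ri = uf_find(parent, i);
        const int rj = uf_find(parent, j);
        if (ri != rj) {
          if (csize[ri] < csize[rj]) {
            parent[ri] = rj;
            csize[rj] += csize[ri];
          } else {
            parent[rj] = ri;
            csize[ri] += csize[rj];
          }
        }
      }
      ++next;
    }
    const double hh = std::pow(h, h_exp) * dh;
    for (size_t a = 0; a < active_list.size(); ++a) {
      const int i = active_list[a];
      const int r = uf_find(parent, i);
      out[i] += std::pow((double)csize[r], e_exp) * hh;
    }
  }
  return out;
}

// Max TFCE score over each row of a matrix of (already null-centred) mean
// maps; used for the sign-flip permutation null distribution. Rows are
// independent permutations, columns are in-mask voxels.
// [[Rcpp::export(name = ".tfce_max_rows")]]
NumericVector tfce_max_rows(NumericMatrix means, IntegerVector adj_ptr,
                            IntegerVector adj_idx, double h_exp, double e_exp,
                            int n_steps, double dh) {
  const int n = means.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    NumericVector row = means.row(r);
    NumericVector t = tfce_graph(row, adj_ptr, adj_idx, h_exp, e_exp,
                                 n_steps, dh);
    double m = 0.0;
    for (int i = 0; i < t.size(); ++i) {
      if (t[i] > m) m = t[i];
    }
    out[r] = m;
  }
  return out;
}
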