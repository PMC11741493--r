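#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Directed nearest-neighbour distances between two point clouds in mm.
// For each row of `from`, the Euclidean distance to the closest row of `to`.
// Points are pre-scaled by voxel spacing on the R side. Brute force with an
// axis-sorted early-exit bound: `to` is sorted on its first coordinate, so a
// candidate whose first-axis gap already exceeds the best distance (and all
// following candidates in that direction) can be skipped.
// [[Rcpp::export]]
NumericVector cpp_nn_distances(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  if (m == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  // sort `to` indices by first coordinate
  std::vector<int> ord(m);
  for (int j = 0; j < m; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return to(a, 0) < to(b, 0); });
  std::vector<double> tx(m), ty(m), tz(m);
  for (int j = 0; j < m; ++j) {
    tx[j] = to(ord[j], 0);
    ty[j] = to(ord[j], 1);
    tz[j] = to(ord[j], 2);
  }
  for (int i = 0; i < n; ++i) {
    const double x = from(i, 0), y = from(i, 1), z = from(i, 2);
    // locate insertion point in sorted first coordinates
    int lo = std::lower_bound(tx.begin(), tx.end(), x) - tx.begin();
    double best = R_PosInf;
    int l = lo - 1, r = lo;
    while (l >= 0 || r < m) {
      // expand toward whichever side has the smaller first-axis gap
      bool take_r;
      if (l < 0) take_r = true;
      else if (r >= m) take_r = false;
      else take_r = (x - tx[l]) > (tx[r] - x);
      int j = take_r ? r : l;
      double dx = tx[j] - x;
      if (dx * dx >= best) {
        // every remaining candidate on this side is at least this far
        if (take_r) r = m; else l = -1;
        continue;
      }
      double dy = ty[j] - y, dz = tz[j] - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (take_r) ++r; else --l;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 3D connected-component labelling with 6-connectivity (face neighbours).
// `mask` is a logical/integer volume in column-major order with dims `dim`.
// Returns an integer volume: 0 background, components numbered 1..k in
// decreasing voxel-count order (label 1 is always the largest component).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes_idx; // component id -> size (1-based stored at id-1)
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_label;
    R_xlen_t count = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = next_label;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++count;
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dxs[6] = {-1, 1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, -1, 1, 0, 0};
      const int dzs[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next_label;
          stack.push_back(w);
        }
      }
    }
    sizes_idx.push_back(count);
  }
  // relabel so that component 1 is the largest
  int k = next_label;
  std::vector<int> order(k);
  for (int i = 0; i < k; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return sizes_idx[a] > sizes_idx[b];
  });
  std::vector<int> remap(k + 1, 0);
  for (int rank = 0; rank < k; ++rank) remap[order[rank] + 1] = rank + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s] != 0) lab[s] = remap[lab[s]];
  lab.attr("dim") = dim;
  return lab;
}
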