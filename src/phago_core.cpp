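#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Mean filter of width 3 along one axis of a 3D column-major array.
// Symmetric reflection at the borders (edge value duplicated).
static void box_pass(const std::vector<double>& in, std::vector<double>& out,
                     int n1, int n2, int n3, int axis) {
  int n = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)n1 : (size_t)n1 * n2;
  // iterate over all lines along `axis`
  size_t o1 = (axis == 0) ? (size_t)n1 : 1;
  int m1 = (axis == 0) ? n2 : n1;
  size_t o2 = (axis == 2) ? (size_t)n1 : (size_t)n1 * n2;
  int m2 = (axis == 2) ? n2 : n3;
  for (int b = 0; b < m2; ++b) {
    for (int a = 0; a < m1; ++a) {
      size_t base = (size_t)a * o1 + (size_t)b * o2;
      if (n == 1) { out[base] = in[base]; continue; }
      // interior
      for (int i = 1; i < n - 1; ++i) {
        size_t p = base + (size_t)i * stride;
        out[p] = (in[p - stride] + in[p] + in[p + stride]) / 3.0;
      }
      // borders: reflect duplicates the edge voxel
      out[base] = (2.0 * in[base] + in[base + stride]) / 3.0;
      size_t last = base + (size_t)(n - 1) * stride;
      out[last] = (2.0 * in[last] + in[last - stride]) / 3.0;
    }
  }
}

// [[Rcpp::export(name = ".box_smooth3_cpp")]]
NumericVector box_smooth3_cpp(NumericVector vol, IntegerVector dim) {
  if (dim.size() != 3) stop("volume must be 3-dimensional");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)vol.size() != n) stop("length does not match dim");
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  box_pass(a, b, n1, n2, n3, 0);
  box_pass(b, a, n1, n2, n3, 1);
  box_pass(a, b, n1, n2, n3, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// Batched 3x3x3 box smoothing over a 4D (x,y,z,t-like) stack: the box is
// applied within each 3D frame independently.
// [[Rcpp::export(name = ".box_smooth3_batch_cpp")]]
NumericVector box_smooth3_batch_cpp(NumericVector vol, IntegerVector dim) {
  if (dim.size() != 4) stop("stack must be 4-dimensional");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2], nt = dim[3];
  size_t fsz = (size_t)n1 * n2 * n3;
  if ((size_t)vol.size() != fsz * nt) stop("length does not match dim");
  NumericVector out(vol.size());
  std::vector<double> a(fsz), b(fsz);
  for (int t = 0; t < nt; ++t) {
    std::copy(vol.begin() + t * fsz, vol.begin() + (t + 1) * fsz, a.begin());
    box_pass(a, b, n1, n2, n3, 0);
    box_pass(b, a, n1, n2, n3, 1);
    box_pass(a, b, n1, n2, n3, 2);
    std::copy(b.begin(), b.end(), out.begin() + t * fsz);
  }
  out.attr("dim") = dim;
  return out;
}

// Connected components on a 3D logical mask, 6- or 26-connectivity.
// Labels are assigned in scan order of the first voxel of each component,
// so the labelling is deterministic and labels are contiguous from 1.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("mask must be 3-dimensional");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)mask.size() != n) stop("length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  std::vector<std::array<int,3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
        nb.push_back({di, dj, dk});
      }
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = cur % n1, j = (cur / n1) % n2, k = cur / ((size_t)n1 * n2);
      for (auto& d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
        size_t t = (size_t)kk * n1 * n2 + (size_t)jj * n1 + ii;
        if (mask[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Batched per-frame 3D labelling of a 4D logical stack; labels restart at 1
// in every frame.
// [[Rcpp::export(name = ".label3d_batch_cpp")]]
IntegerVector label3d_batch_cpp(LogicalVector mask, IntegerVector dim,
                                int connectivity) {
  if (dim.size() != 4) stop("stack must be 4-dimensional");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2], nt = dim[3];
  size_t fsz = (size_t)n1 * n2 * n3;
  if ((size_t)mask.size() != fsz * nt) stop("length does not match dim");
  IntegerVector out(mask.size());
  IntegerVector d3 = IntegerVector::create(n1, n2, n3);
  LogicalVector fr(fsz);
  for (int t = 0; t < nt; ++t) {
    std::copy(mask.begin() + t * fsz, mask.begin() + (t + 1) * fsz, fr.begin());
    IntegerVector lab = label3d_cpp(fr, d3, connectivity);
    std::copy(lab.begin(), lab.end(), out.begin() + t * fsz);
  }
  out.attr("dim") = dim;
  return out;
}

// O(n^3) Hungarian algorithm (shortest augmenting path formulation) on a
// rectangular cost matrix with nr <= nc after padding by the caller.
// cost is column-major nr x nc; entries >= big are treated as forbidden.
// Returns for each row the assigned column (1-based) or NA if only a
// forbidden assignment would remain.
// [[Rcpp::export(name = ".hungarian_cpp")]]
IntegerVector hungarian_cpp(NumericMatrix cost, double forbidden) {
  int nr = cost.nrow(), nc = cost.ncol();
  if (nr == 0 || nc == 0) return IntegerVector(nr, NA_INTEGER);
  // pad to square with zeros (dummy columns/rows absorb unmatched)
  int n = std::max(nr, nc);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> a((size_t)(n + 1) * (n + 1), 0.0);
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= n; ++j) {
      double c = 0.0;
      if (i <= nr && j <= nc) {
        c = cost(i - 1, j - 1);
        if (c >= forbidden) c = forbidden;  // forbidden, but finite so padding works
      }
      a[(size_t)i * (n + 1) + j] = c;
    }
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a[(size_t)i0 * (n + 1) + j] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector res(nr, NA_INTEGER);
  for (int j = 1; j <= n; ++j) {
    int i = p[j];
    if (i >= 1 && i <= nr && j <= nc && cost(i - 1, j - 1) < forbidden)
      res[i - 1] = j;
  }
  return res;
}
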