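#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- union-find -----------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
  int root = i;
  while (parent[root] != root) root = parent[root];
  while (parent[i] != root) { int next = parent[i]; parent[i] = root; i = next; }
  return root;
}

static inline void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
}

// [[Rcpp::export(name = ".cc_label3d_cpp")]]
IntegerVector cc_label3d_cpp(LogicalVector mask, IntegerVector dims,
                             int connectivity) {
  // Label foreground voxels of a 3-D mask. dims = c(d1, d2, d3) in R's
  // column-major order; linear index i = i1 + d1*(i2 + d2*i3).
  // connectivity: 6 (faces) or 26 (faces+edges+corners).
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // forward half-neighbourhood so each pair is visited once
  std::vector<std::array<int,3>> offs;
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1) {
        if (o1 == 0 && o2 == 0 && o3 == 0) continue;
        int manh = std::abs(o1) + std::abs(o2) + std::abs(o3);
        if (connectivity == 6 && manh != 1) continue;
        // keep lexicographically positive offsets only
        if (o3 > 0 || (o3 == 0 && (o2 > 0 || (o2 == 0 && o1 > 0))))
          offs.push_back({o1, o2, o3});
      }

  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        R_xlen_t idx = i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
        if (!mask[idx]) continue;
        for (auto &o : offs) {
          int j1 = i1 + o[0], j2 = i2 + o[1], j3 = i3 + o[2];
          if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
            continue;
          R_xlen_t jdx = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
          if (mask[jdx]) uf_union(parent, (int)idx, (int)jdx);
        }
      }

  // relabel roots as consecutive positive ids, background 0
  IntegerVector out(n, 0);
  std::vector<int> newlab(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, (int)i);
    if (newlab[r] == 0) newlab[r] = ++next;
    out[i] = newlab[r];
  }
  out.attr("n_labels") = next;
  return out;
}

// ---- exact squared Euclidean distance transform ---------------------------
// Felzenszwalb & Huttenlocher lower-envelope algorithm, applied separably
// along each axis with anisotropic sampling (voxel spacing in mm).

static void dt1d(const double *f, double *d, int n, double step,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  // Euclidean distance (mm) from every voxel to the nearest background
  // (mask == FALSE) voxel centre. spacing = per-axis step (d1, d2, d3 order).
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  // large finite sentinel instead of Inf keeps the lower-envelope
  // intersection arithmetic NaN-free on all-foreground scan lines
  const double BIG = 1e30;

  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dcol(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // axis 1
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2) {
      R_xlen_t base = (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
      for (int i1 = 0; i1 < d1; ++i1) f[i1] = g[base + i1];
      dt1d(f.data(), dcol.data(), d1, spacing[0], v, z);
      for (int i1 = 0; i1 < d1; ++i1) g[base + i1] = dcol[i1];
    }
  // axis 2
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * d2 * (R_xlen_t)i3;
      for (int i2 = 0; i2 < d2; ++i2) f[i2] = g[base + (R_xlen_t)d1 * i2];
      dt1d(f.data(), dcol.data(), d2, spacing[1], v, z);
      for (int i2 = 0; i2 < d2; ++i2) g[base + (R_xlen_t)d1 * i2] = dcol[i2];
    }
  // axis 3
  const R_xlen_t stride3 = (R_xlen_t)d1 * d2;
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * i2;
      for (int i3 = 0; i3 < d3; ++i3) f[i3] = g[base + stride3 * i3];
      dt1d(f.data(), dcol.data(), d3, spacing[2], v, z);
      for (int i3 = 0; i3 < d3; ++i3) g[base + stride3 * i3] = dcol[i3];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
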