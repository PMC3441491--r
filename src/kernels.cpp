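#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling on a logical volume with dims (ny, nx, nz).
// slicewise = true labels 8-neighbor components within each slice (labels are
// unique across slices); slicewise = false labels 26-neighbor 3D components.
// Label ids are assigned in raster order of the first voxel reached, so the
// result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, bool slicewise) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  const int dzlo = slicewise ? 0 : -1, dzhi = slicewise ? 0 : 1;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      const int y = v % ny, x = (v / ny) % nx, z = v / (ny * nx);
      for (int dz = dzlo; dz <= dzhi; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dz && !dx && !dy) continue;
            const int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            const int w = yy + ny * (xx + nx * zz);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

static inline int nbr8(const LogicalMatrix& m, int y, int x, int dy, int dx) {
  const int yy = y + dy, xx = x + dx;
  if (yy < 0 || yy >= m.nrow() || xx < 0 || xx >= m.ncol()) return 0;
  return m(yy, xx) ? 1 : 0;
}

// Zhang-Suen two-subiteration thinning of one binary slice; reduces blobs to
// 8-connected unit-width skeletons and is the identity on unit-width curves.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  LogicalMatrix m = clone(img);
  const int ny = m.nrow(), nx = m.ncol();
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          if (!m(y, x)) continue;
          // neighbours P2..P9 clockwise from north (y-1)
          const int p2 = nbr8(m, y, x, -1, 0), p3 = nbr8(m, y, x, -1, 1),
                    p4 = nbr8(m, y, x, 0, 1),  p5 = nbr8(m, y, x, 1, 1),
                    p6 = nbr8(m, y, x, 1, 0),  p7 = nbr8(m, y, x, 1, -1),
                    p8 = nbr8(m, y, x, 0, -1), p9 = nbr8(m, y, x, -1, -1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                        (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                        (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                        (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(y, x));
        }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          m(kill[i].first, kill[i].second) = false;
      }
    }
  }
  return m;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform on sampled grid
// positions with spacing w. f holds squared distances on input, overwritten.
// "No site" is encoded as the large finite DT_BIG so the standard lower-
// envelope recursion needs no special casing.
static const double DT_BIG = 1e20;

static void dt1d(std::vector<double>& f, double w, int n,
                 std::vector<int>& v, std::vector<double>& zb,
                 std::vector<double>& out) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * w;
    double s;
    for (;;) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= zb[k]) { --k; continue; }
      break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (zb[k + 1] < xq) ++k;
    const double d = xq - v[k] * w;
    out[q] = d * d + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = out[q];
}

// Exact Euclidean distance transform of a logical volume (dims ny,nx,nz) with
// anisotropic spacing (wy, wx, wz): distance from each foreground voxel to the
// nearest background voxel center, in physical units. Background voxels get 0.
// Infinite where the volume has no background voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double wy = spacing[0], wx = spacing[1], wz = spacing[2];
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? DT_BIG : 0.0;
  const int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
      for (int y = 0; y < ny; ++y) f[y] = d[base + y];
      dt1d(f, wy, ny, v, zb, out);
      for (int y = 0; y < ny; ++y) d[base + y] = f[y];
    }
  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)];
      dt1d(f, wx, nx, v, zb, out);
      for (int x = 0; x < nx; ++x) d[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)] = f[x];
    }
  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)];
      dt1d(f, wz, nz, v, zb, out);
      for (int z = 0; z < nz; ++z) d[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)] = f[z];
    }
  for (R_xlen_t i = 0; i < d.size(); ++i)
    d[i] = (d[i] >= 1e19) ? R_PosInf : std::sqrt(d[i]);
  return d;
}

// Per-row minimum Euclidean distance from each query point to a reference
// point set. Exact brute force (the sizes used here are modest).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow(), dcol = query.ncol();
  NumericVector res(nq);
  for (int i = 0; i < nq; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nr; ++j) {
      double s = 0.0;
      for (int c = 0; c < dcol; ++c) {
        const double t = query(i, c) - ref(j, c);
        s += t * t;
        if (s >= best) break;
      }
      if (s < best) best = s;
    }
    res[i] = std::sqrt(best);
  }
  return res;
}

// Exact closest pair between two point sets: returns 1-based row indices and
// the distance.
// [[Rcpp::export]]
List cpp_closest_pair(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), dcol = a.ncol();
  double best = std::numeric_limits<double>::infinity();
  int bi = 0, bj = 0;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int c = 0; c < dcol; ++c) {
        const double t = a(i, c) - b(j, c);
        s += t * t;
        if (s >= best) break;
      }
      if (s < best) { best = s; bi = i; bj = j; }
    }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1,
                      _["dist"] = std::sqrt(best));
}
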