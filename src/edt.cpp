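#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower-envelope algorithm), with samples at physical
// positions i*h so anisotropic voxel spacing is handled exactly.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = 0.0;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = f[v[k]] == INF ? INF : dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance transform (in physical units) of a 3D source
// mask. Returns distances in the same units as `spacing`; +Inf where the
// source is empty along every axis (i.e. an all-zero mask).
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector src, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = src[i] ? 0.0 : INF;

  std::vector<double> f, d;

  // pass along x (fastest-varying index)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
    }

  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = D[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) D[base + (R_xlen_t)z * nx * ny] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = D[i] == INF ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = dim;
  return out;
}

// Minimum squared distance from each query point to a polyline given by
// ordered control points (columns of `pts`, 3 x m). Used for analytic
// phantom ground truth, independent of any voxel distance transform.
// [[Rcpp::export(name = ".polyline_dist")]]
NumericVector polyline_dist(NumericMatrix query, NumericMatrix pts) {
  int nq = query.nrow();
  int m = pts.ncol();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = INF;
    for (int s = 0; s + 1 < m; ++s) {
      double ax = pts(0, s), ay = pts(1, s), az = pts(2, s);
      double bx = pts(0, s + 1), by = pts(1, s + 1), bz = pts(2, s + 1);
      double vx = bx - ax, vy = by - ay, vz = bz - az;
      double wx = qx - ax, wy = qy - ay, wz = qz - az;
      double vv = vx * vx + vy * vy + vz * vz;
      double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    if (m == 1) {
      double dx = qx - pts(0, 0), dy = qy - pts(1, 0), dz = qz - pts(2, 0);
      best = dx * dx + dy * dy + dz * dz;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
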