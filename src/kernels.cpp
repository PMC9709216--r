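// Low-level voxel kernels: separable filters, per-voxel symmetric 3x3
// eigendecomposition, Euclidean distance transform, capsule rasterisation.
// All arrays are passed as flat double vectors in R's column-major layout
// with explicit dims (nx, ny, nz).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// Running box sum of half-width h along one axis, window clipped at the
// volume edge (no padding: edge sums are over fewer voxels).
static void box_axis(const std::vector<double>& in, std::vector<double>& out,
                     int nx, int ny, int nz, int axis, int h) {
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len), acc(len);
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < n[ob]; ++b) {
    for (int a = 0; a < n[oa]; ++a) {
      int c[3]; c[oa] = a; c[ob] = b;
      for (int i = 0; i < len; ++i) {
        c[axis] = i;
        line[i] = in[idx3(c[0], c[1], c[2], nx, ny)];
      }
      double s = 0.0;
      for (int i = 0; i <= std::min(h, len - 1); ++i) s += line[i];
      for (int i = 0; i < len; ++i) {
        acc[i] = s;
        int add = i + h + 1, rem = i - h;
        if (add < len) s += line[add];
        if (rem >= 0) s -= line[rem];
      }
      for (int i = 0; i < len; ++i) {
        c[axis] = i;
        out[idx3(c[0], c[1], c[2], nx, ny)] = acc[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector arr, IntegerVector dims, int window) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int h = (window - 1) / 2;
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  box_axis(a, b, nx, ny, nz, 0, h);
  box_axis(b, a, nx, ny, nz, 1, h);
  box_axis(a, b, nx, ny, nz, 2, h);
  NumericVector out(b.begin(), b.end());
  return out;
}

// Separable correlation with a symmetric 1D kernel, reflecting at edges.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& k) {
  int n[3] = {nx, ny, nz};
  int len = n[axis], h = ((int)k.size() - 1) / 2;
  std::vector<double> line(len);
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < n[ob]; ++b) {
    for (int a = 0; a < n[oa]; ++a) {
      int c[3]; c[oa] = a; c[ob] = b;
      for (int i = 0; i < len; ++i) {
        c[axis] = i;
        line[i] = in[idx3(c[0], c[1], c[2], nx, ny)];
      }
      for (int i = 0; i < len; ++i) {
        double s = 0.0;
        for (int j = -h; j <= h; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= len) p = 2 * len - p - 1;
          s += k[j + h] * line[p];
        }
        c[axis] = i;
        out[idx3(c[0], c[1], c[2], nx, ny)] = s;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_sep(NumericVector arr, IntegerVector dims,
                           NumericVector kernel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> k(kernel.begin(), kernel.end());
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  conv_axis(a, b, nx, ny, nz, 0, k);
  conv_axis(b, a, nx, ny, nz, 1, k);
  conv_axis(a, b, nx, ny, nz, 2, k);
  return NumericVector(b.begin(), b.end());
}

// Per-voxel eigendecomposition of the symmetric tensor field given by its
// six unique components. Eigenvalues returned in descending order
// (l1 >= l2 >= l3); v3 spans the smallest eigenvalue (the fiber axis for a
// structure tensor). Voxels where compute[i] is false are skipped (NaN out).
// [[Rcpp::export]]
List cpp_eig3_field(NumericVector xx, NumericVector xy, NumericVector xz,
                    NumericVector yy, NumericVector yz, NumericVector zz,
                    LogicalVector compute, bool full_vectors) {
  R_xlen_t n = xx.size();
  NumericVector l1(n, NA_REAL), l2(n, NA_REAL), l3(n, NA_REAL);
  NumericVector v3x(n, NA_REAL), v3y(n, NA_REAL), v3z(n, NA_REAL);
  NumericVector v1x, v1y, v1z, v2x, v2y, v2z;
  if (full_vectors) {
    v1x = NumericVector(n, NA_REAL); v1y = NumericVector(n, NA_REAL);
    v1z = NumericVector(n, NA_REAL); v2x = NumericVector(n, NA_REAL);
    v2y = NumericVector(n, NA_REAL); v2z = NumericVector(n, NA_REAL);
  }
  arma::mat33 J;
  arma::vec3 ev;
  arma::mat33 V;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!compute[i]) continue;
    J(0,0) = xx[i]; J(0,1) = xy[i]; J(0,2) = xz[i];
    J(1,0) = xy[i]; J(1,1) = yy[i]; J(1,2) = yz[i];
    J(2,0) = xz[i]; J(2,1) = yz[i]; J(2,2) = zz[i];
    arma::eig_sym(ev, V, J);           // ascending
    l1[i] = ev(2); l2[i] = ev(1); l3[i] = ev(0);
    v3x[i] = V(0,0); v3y[i] = V(1,0); v3z[i] = V(2,0);
    if (full_vectors) {
      v1x[i] = V(0,2); v1y[i] = V(1,2); v1z[i] = V(2,2);
      v2x[i] = V(0,1); v2y[i] = V(1,1); v2z[i] = V(2,1);
    }
  }
  List out = List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                          _["v3x"] = v3x, _["v3y"] = v3y, _["v3z"] = v3z);
  if (full_vectors) {
    out["v1x"] = v1x; out["v1y"] = v1y; out["v1z"] = v1z;
    out["v2x"] = v2x; out["v2y"] = v2y; out["v2z"] = v2z;
  }
  return out;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform, with samples at
// x_i = i * s (anisotropic spacing supported).
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  // lower envelope over parabolas with finite height only (infinite ones
  // can never attain the minimum)
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    double xq = q * s;
    double sI = 0.0;
    while (k >= 0) {
      double xv = v[k] * s;
      sI = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sI <= z[k]) { --k; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INFINITY; }
    else { ++k; v[k] = q; z[k] = sI; }
    z[k + 1] = INFINITY;
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INFINITY; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// Euclidean distance (physical units) from every voxel to the nearest seed.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector seed, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> f(n);
  for (R_xlen_t i = 0; i < n; ++i) f[i] = seed[i] ? 0.0 : INFINITY;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  int nn[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int len = nn[axis];
    if (len < 2) continue;
    double s = spacing[axis];
    int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
    for (int b = 0; b < nn[ob]; ++b) {
      for (int a = 0; a < nn[oa]; ++a) {
        int c[3]; c[oa] = a; c[ob] = b;
        bool allInf = true;
        for (int i = 0; i < len; ++i) {
          c[axis] = i;
          line[i] = f[idx3(c[0], c[1], c[2], nx, ny)];
          if (std::isfinite(line[i])) allInf = false;
        }
        if (allInf) continue;
        std::vector<double> fl(line.begin(), line.begin() + len);
        dt1d(fl, s, d, v, z);
        for (int i = 0; i < len; ++i) {
          c[axis] = i;
          f[idx3(c[0], c[1], c[2], nx, ny)] = d[i];
        }
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::isfinite(f[i]) ? std::sqrt(f[i]) : R_PosInf;
  return out;
}

// Paint bright capsules (cylinders with hemispherical caps) into a volume by
// max-compositing (rods are opaque: overlaps do not add up, so no spurious
// internal intensity edges). centres/axes are n x 3 in voxel units
// (0-based), axes unit-norm.
// [[Rcpp::export]]
NumericVector cpp_paint_capsules(NumericVector vol, IntegerVector dims,
                                 NumericMatrix centres, NumericMatrix axes,
                                 double half_len, double radius,
                                 double intensity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(vol);
  double reach = half_len + radius;
  double r2 = radius * radius;
  for (int r = 0; r < centres.nrow(); ++r) {
    double cx = centres(r,0), cy = centres(r,1), cz = centres(r,2);
    double ax = axes(r,0), ay = axes(r,1), az = axes(r,2);
    int x0 = std::max(0, (int)std::floor(cx - reach));
    int x1 = std::min(nx - 1, (int)std::ceil(cx + reach));
    int y0 = std::max(0, (int)std::floor(cy - reach));
    int y1 = std::min(ny - 1, (int)std::ceil(cy + reach));
    int z0 = std::max(0, (int)std::floor(cz - reach));
    int z1 = std::min(nz - 1, (int)std::ceil(cz + reach));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double px = x - cx, py = y - cy, pz = z - cz;
          double t = px * ax + py * ay + pz * az;
          if (t > half_len) t = half_len;
          if (t < -half_len) t = -half_len;
          double dx = px - t * ax, dy = py - t * ay, dz = pz - t * az;
          double d2 = dx * dx + dy * dy + dz * dz;
          R_xlen_t o = idx3(x, y, z, nx, ny);
          if (d2 <= r2 && out[o] < intensity) out[o] = intensity;
        }
  }
  return out;
}
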