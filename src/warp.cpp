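#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D column-major volume at 0-based voxel
// coordinates (x, y, z).  Coordinates more than half a voxel outside the
// grid return `def`; inside, edge values are clamped.
static inline double tri(const double *v, const int nx, const int ny,
                         const int nz, double x, double y, double z,
                         const double def) {
  if (!R_finite(x) || !R_finite(y) || !R_finite(z))
    return def;
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return def;
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  const int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  const int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  const int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sxy = (size_t)nx * ny;
#define V(i, j, k) v[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
  const double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  const double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  const double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  const double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample through the affine pull map q = A p + t (0-based voxel
// coords).  `src_dim` are the dimensions of `vol`; `out_dim` those of
// the output grid the map is evaluated on (they differ when resampling
// between resolution levels).
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector vol, IntegerVector src_dim,
                              IntegerVector out_dim, NumericMatrix A,
                              NumericVector t, double def) {
  const int sx_n = src_dim[0], sy_n = src_dim[1], sz_n = src_dim[2];
  const int nx = out_dim[0], ny = out_dim[1], nz = out_dim[2];
  if ((R_xlen_t)sx_n * sy_n * sz_n != vol.size())
    stop("source volume length does not match src_dim");
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *v = vol.begin();
  double *o = out.begin();
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        const double sx = a00 * i + a01 * j + a02 * k + t[0];
        const double sy = a10 * i + a11 * j + a12 * k + t[1];
        const double sz = a20 * i + a21 * j + a22 * k + t[2];
        o[idx] = tri(v, sx_n, sy_n, sz_n, sx, sy, sz, def);
      }
  out.attr("dim") = out_dim;
  return out;
}

// Resample through the displacement pull map q = p + u(p), u in voxels.
// [[Rcpp::export]]
NumericVector cpp_warp_field(NumericVector vol, IntegerVector dim,
                             NumericVector ux, NumericVector uy,
                             NumericVector uz, double def) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n || ux.size() != n || uy.size() != n ||
      uz.size() != n)
    stop("volume and field lengths must match dim");
  NumericVector out(n);
  const double *v = vol.begin();
  double *o = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        o[idx] = tri(v, nx, ny, nz, i + ux[idx], j + uy[idx], k + uz[idx],
                     def);
      }
  out.attr("dim") = dim;
  return out;
}

// Composed pull map: q = p + u(p) then r = A q + t; sample vol at r.
// Single interpolation of `vol`, used for label propagation through
// deformable-then-rigid composition.
// [[Rcpp::export]]
NumericVector cpp_warp_affine_field(NumericVector vol, IntegerVector dim,
                                    NumericMatrix A, NumericVector t,
                                    NumericVector ux, NumericVector uy,
                                    NumericVector uz, double def) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n || ux.size() != n || uy.size() != n ||
      uz.size() != n)
    stop("volume and field lengths must match dim");
  NumericVector out(n);
  const double *v = vol.begin();
  double *o = out.begin();
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        const double qx = i + ux[idx], qy = j + uy[idx], qz = k + uz[idx];
        const double sx = a00 * qx + a01 * qy + a02 * qz + t[0];
        const double sy = a10 * qx + a11 * qy + a12 * qz + t[1];
        const double sz = a20 * qx + a21 * qy + a22 * qz + t[2];
        o[idx] = tri(v, nx, ny, nz, sx, sy, sz, def);
      }
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing with replicated edges; sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim,
                           double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector out(clone(vol));
  if (sigma <= 0)
    return out;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double wsum = 0.0;
  for (int d = -r; d <= r; ++d) {
    w[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    wsum += w[d + r];
  }
  for (int d = 0; d <= 2 * r; ++d)
    w[d] /= wsum;

  std::vector<double> buf(n);
  double *a = out.begin();
  double *b = buf.data();
  const size_t sxy = (size_t)nx * ny;

  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t base = (size_t)nx * j + sxy * k;
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int d = -r; d <= r; ++d) {
          int ii = i + d;
          if (ii < 0) ii = 0;
          if (ii >= nx) ii = nx - 1;
          s += w[d + r] * a[base + ii];
        }
        b[base + i] = s;
      }
    }
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const size_t base = (size_t)i + sxy * k;
      for (int j = 0; j < ny; ++j) {
        double s = 0.0;
        for (int d = -r; d <= r; ++d) {
          int jj = j + d;
          if (jj < 0) jj = 0;
          if (jj >= ny) jj = ny - 1;
          s += w[d + r] * b[base + (size_t)nx * jj];
        }
        a[base + (size_t)nx * j] = s;
      }
    }
  // z axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const size_t base = (size_t)i + (size_t)nx * j;
      for (int k = 0; k < nz; ++k) {
        double s = 0.0;
        for (int d = -r; d <= r; ++d) {
          int kk = k + d;
          if (kk < 0) kk = 0;
          if (kk >= nz) kk = nz - 1;
          s += w[d + r] * a[base + sxy * kk];
        }
        b[base + sxy * k] = s;
      }
    }
  std::copy(buf.begin(), buf.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
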