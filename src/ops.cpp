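#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Trilinear interpolation of a 3-D array at continuous 0-based voxel
// coordinates. Points outside the grid get `fill`.
static inline double trilerp(const double *v, int nx, int ny, int nz,
                             double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t i0 = x0 * sx + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
  double c000 = v[i0],           c100 = v[i0 + sx];
  double c010 = v[i0 + sy],      c110 = v[i0 + sx + sy];
  double c001 = v[i0 + sz],      c101 = v[i0 + sx + sz];
  double c011 = v[i0 + sy + sz], c111 = v[i0 + sx + sy + sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pts, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = trilerp(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), fill);
  return out;
}

// Catmull-Rom cubic kernel
static inline double cr_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 - t * t * (2.5 - 1.5 * t);
  if (t < 2.0) return 2.0 - t * (4.0 - t * (2.5 - 0.5 * t));
  return 0.0;
}

// Separable Catmull-Rom interpolation; falls back to trilinear within one
// voxel of the grid border.
static inline double tricubic(const double *v, int nx, int ny, int nz,
                              double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 < 1 || y0 < 1 || z0 < 1 || x0 > nx - 3 || y0 > ny - 3 || z0 > nz - 3)
    return trilerp(v, nx, ny, nz, x, y, z, fill);
  double wx[4], wy[4], wz[4];
  for (int m = 0; m < 4; m++) {
    wx[m] = cr_w(x - (x0 - 1 + m));
    wy[m] = cr_w(y - (y0 - 1 + m));
    wz[m] = cr_w(z - (z0 - 1 + m));
  }
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double acc = 0;
  for (int c = 0; c < 4; c++) {
    double accy = 0;
    for (int b = 0; b < 4; b++) {
      const double *row = v + (R_xlen_t)(x0 - 1) +
        (R_xlen_t)(y0 - 1 + b) * sy + (R_xlen_t)(z0 - 1 + c) * sz;
      double accx = row[0] * wx[0] + row[1] * wx[1] + row[2] * wx[2] +
        row[3] * wx[3];
      accy += accx * wy[b];
    }
    acc += accy * wz[c];
  }
  return acc;
}

// Resample a volume onto an output grid through an affine map in index
// space: source_index = A * [i, j, k, 1]' for 0-based output index (i,j,k).
// interp: 0 = trilinear, 1 = nearest (required for label/mask images),
// 2 = Catmull-Rom cubic.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dims,
                                  IntegerVector out_dims, NumericMatrix A,
                                  double fill, int interp) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *v = REAL(vol);
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; k++) {
    for (int j = 0; j < oy; j++) {
      double xj = a01 * j + a03 + a02 * k;
      double yj = a11 * j + a13 + a12 * k;
      double zj = a21 * j + a23 + a22 * k;
      for (int i = 0; i < ox; i++, idx++) {
        double x = a00 * i + xj, y = a10 * i + yj, z = a20 * i + zj;
        if (interp == 1) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y),
              zi = (int)std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
            out[idx] = fill;
          else
            out[idx] = v[xi + (R_xlen_t)yi * nx + (R_xlen_t)zi * nx * ny];
        } else if (interp == 2) {
          out[idx] = tricubic(v, nx, ny, nz, x, y, z, fill);
        } else {
          out[idx] = trilerp(v, nx, ny, nz, x, y, z, fill);
        }
      }
    }
  }
  return out;
}

static void gauss_kernel(double sigma, std::vector<double> &k) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  k.assign(2 * r + 1, 0.0);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    double w = std::exp(-0.5 * i * i / (sigma * sigma));
    k[i + r] = w;
    s += w;
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// Border handling: kernel renormalized over in-grid support.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(REAL(vol), REAL(vol) + n), tmp(n);
  int dn[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    std::vector<double> ker;
    gauss_kernel(sg, ker);
    int r = ((int)ker.size() - 1) / 2;
    int len = dn[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int d1 = (ax == 0) ? 1 : 0;
    int d2 = (ax == 2) ? 1 : 2;
    for (int b = 0; b < dn[d2]; b++) {
      for (int a = 0; a < dn[d1]; a++) {
        R_xlen_t base = (R_xlen_t)a * stride[d1] + (R_xlen_t)b * stride[d2];
        for (int p = 0; p < len; p++) {
          double acc = 0, wsum = 0;
          int lo = p - r < 0 ? -p : -r;
          int hi = p + r > len - 1 ? len - 1 - p : r;
          for (int q = lo; q <= hi; q++) {
            double w = ker[q + r];
            acc += w * buf[base + (R_xlen_t)(p + q) * st];
            wsum += w;
          }
          tmp[base + (R_xlen_t)p * st] = acc / wsum;
        }
      }
    }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// 6-connected component labelling of a logical/integer mask.
// Returns integer labels 1..ncomp (0 = background), column-major 3-D.
// [[Rcpp::export]]
IntegerVector cpp_connected_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / sz);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; d++) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t q = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sz;
        if (mask[q] && !lab[q]) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("ncomp") = cur;
  return lab;
}

// Mean over the 3x3x3 neighbourhood (truncated at borders); the local
// averaging step of the spatially adaptive prior field.
// [[Rcpp::export]]
NumericVector cpp_boxmean3(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *v = REAL(vol);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; k++) {
    int k0 = k > 0 ? k - 1 : 0, k1 = k < nz - 1 ? k + 1 : nz - 1;
    for (int j = 0; j < ny; j++) {
      int j0 = j > 0 ? j - 1 : 0, j1 = j < ny - 1 ? j + 1 : ny - 1;
      for (int i = 0; i < nx; i++, idx++) {
        int i0 = i > 0 ? i - 1 : 0, i1 = i < nx - 1 ? i + 1 : nx - 1;
        double acc = 0;
        int cnt = 0;
        for (int kk = k0; kk <= k1; kk++)
          for (int jj = j0; jj <= j1; jj++)
            for (int ii = i0; ii <= i1; ii++) {
              acc += v[ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * sz];
              cnt++;
            }
        out[idx] = acc / cnt;
      }
    }
  }
  return out;
}
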