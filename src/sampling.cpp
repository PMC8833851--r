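#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest sampling of a 3-D volume at arbitrary voxel coordinates.
// coords: N x 3 matrix of 0-based voxel coordinates. Out-of-field -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector data, IntegerVector dims,
                                NumericMatrix coords, bool nearest,
                                double fill = 0.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *d = REAL(data);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t i = 0; i < n; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (nearest) {
      long ix = lround(x), iy = lround(y), iz = lround(z);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
        out[i] = fill;
      } else {
        out[i] = d[ix * sx + iy * sy + iz * sz];
      }
    } else {
      // trilinear; treat anything whose 8-neighbourhood leaves the grid as outside
      double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
      long ix = (long)fx, iy = (long)fy, iz = (long)fz;
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1) {
        // allow exact top boundary
        if (x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 && z <= nz - 1) {
          long cx = ix >= nx - 1 ? nx - 2 : ix;
          long cy = iy >= ny - 1 ? ny - 2 : iy;
          long cz = iz >= nz - 1 ? nz - 2 : iz;
          double tx = x - cx, ty = y - cy, tz = z - cz;
          const double *p = d + cx * sx + cy * sy + cz * sz;
          double c00 = p[0] * (1 - tx) + p[sx] * tx;
          double c10 = p[sy] * (1 - tx) + p[sy + sx] * tx;
          double c01 = p[sz] * (1 - tx) + p[sz + sx] * tx;
          double c11 = p[sz + sy] * (1 - tx) + p[sz + sy + sx] * tx;
          out[i] = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                   (c01 * (1 - ty) + c11 * ty) * tz;
        } else {
          out[i] = fill;
        }
      } else {
        double tx = x - fx, ty = y - fy, tz = z - fz;
        const double *p = d + ix * sx + iy * sy + iz * sz;
        double c00 = p[0] * (1 - tx) + p[sx] * tx;
        double c10 = p[sy] * (1 - tx) + p[sy + sx] * tx;
        double c01 = p[sz] * (1 - tx) + p[sz + sx] * tx;
        double c11 = p[sz + sy] * (1 - tx) + p[sz + sy + sx] * tx;
        out[i] = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                 (c01 * (1 - ty) + c11 * ty) * tz;
      }
    }
  }
  return out;
}

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  // truncated discrete Gaussian, renormalized at borders
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) { dst = src; return; }
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;

  const long sx = 1, sy = nx, sz = (long)nx * ny;
  long stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);

  for (int a = 0; a < (axis == 0 ? ny : nx); ++a) {
    for (int b = 0; b < (axis == 2 ? ny : nz); ++b) {
      long base;
      if (axis == 0)      base = a * sy + b * sz;
      else if (axis == 1) base = a * sx + b * sz;
      else                base = a * sx + b * sy;
      for (int i = 0; i < len; ++i) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          double w = k[j - i + r];
          acc += w * src[base + (long)j * stride];
          wsum += w;
        }
        dst[base + (long)i * stride] = acc / wsum;
      }
    }
  }
}

// Separable 3-D Gaussian blur; sigma given per axis in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dims,
                                NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(data.begin(), data.end()), b(a.size());
  if (sigma_vox[0] > 0) { blur_axis(a, b, nx, ny, nz, 0, sigma_vox[0]); std::swap(a, b); }
  if (sigma_vox[1] > 0) { blur_axis(a, b, nx, ny, nz, 1, sigma_vox[1]); std::swap(a, b); }
  if (sigma_vox[2] > 0) { blur_axis(a, b, nx, ny, nz, 2, sigma_vox[2]); std::swap(a, b); }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Joint histogram with hard bin assignment over paired samples.
// Values outside [lo, hi] are clamped into the edge bins.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int bins,
                             double alo, double ahi, double blo, double bhi) {
  NumericMatrix h(bins, bins);
  const R_xlen_t n = a.size();
  const double ascale = (ahi > alo) ? bins / (ahi - alo) : 0.0;
  const double bscale = (bhi > blo) ? bins / (bhi - blo) : 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int ia = (int)((a[i] - alo) * ascale);
    int ib = (int)((b[i] - blo) * bscale);
    if (ia < 0) ia = 0; else if (ia >= bins) ia = bins - 1;
    if (ib < 0) ib = 0; else if (ib >= bins) ib = bins - 1;
    h(ia, ib) += 1.0;
  }
  return h;
}

// Joint histogram with linear partial-volume bin assignment: each sample
// spreads bilinear weights over the 2 x 2 neighbouring bins, giving a
// metric that varies smoothly with intensity changes.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist_pv(NumericVector a, NumericVector b, int bins,
                                double alo, double ahi, double blo, double bhi) {
  NumericMatrix h(bins, bins);
  const R_xlen_t n = a.size();
  const double ascale = (ahi > alo) ? (bins - 1) / (ahi - alo) : 0.0;
  const double bscale = (bhi > blo) ? (bins - 1) / (bhi - blo) : 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double ua = (a[i] - alo) * ascale;
    double ub = (b[i] - blo) * bscale;
    if (ua < 0) ua = 0; else if (ua > bins - 1) ua = bins - 1;
    if (ub < 0) ub = 0; else if (ub > bins - 1) ub = bins - 1;
    int ia = (int)ua, ib = (int)ub;
    if (ia >= bins - 1) ia = bins - 2;
    if (ib >= bins - 1) ib = bins - 2;
    double fa = ua - ia, fb = ub - ib;
    h(ia, ib)         += (1 - fa) * (1 - fb);
    h(ia + 1, ib)     += fa * (1 - fb);
    h(ia, ib + 1)     += (1 - fa) * fb;
    h(ia + 1, ib + 1) += fa * fb;
  }
  return h;
}
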