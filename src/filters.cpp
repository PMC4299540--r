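#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// All kernels operate on 3D arrays stored in R's column-major order with
// dimensions (nx, ny, nz); x is the fastest-varying index. Border handling is
// edge replication (index clamping) throughout.

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Separable correlation along one axis: out(i) = sum_u k(u) * in(i + u - r),
// u = 0..len-1, r = (len-1)/2, indices clamped to the volume.
static void conv_axis(const double *in, double *out,
                      int nx, int ny, int nz,
                      const double *k, int klen, int axis) {
  int r = (klen - 1) / 2;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        if (axis == 0) {
          for (int u = 0; u < klen; ++u) {
            int xi = clampi(x + u - r, nx);
            acc += k[u] * in[xi + (size_t)nx * (y + (size_t)ny * z)];
          }
        } else if (axis == 1) {
          for (int u = 0; u < klen; ++u) {
            int yi = clampi(y + u - r, ny);
            acc += k[u] * in[x + (size_t)nx * (yi + (size_t)ny * z)];
          }
        } else {
          for (int u = 0; u < klen; ++u) {
            int zi = clampi(z + u - r, nz);
            acc += k[u] * in[x + (size_t)nx * (y + (size_t)ny * zi)];
          }
        }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sepconv3(NumericVector img, IntegerVector dim,
                           NumericVector kx, NumericVector ky,
                           NumericVector kz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> tmp(n);
  conv_axis(img.begin(), out.begin(), nx, ny, nz, kx.begin(), kx.size(), 0);
  conv_axis(out.begin(), tmp.data(), nx, ny, nz, ky.begin(), ky.size(), 1);
  conv_axis(tmp.data(), out.begin(), nx, ny, nz, kz.begin(), kz.size(), 2);
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector img, IntegerVector dim, int size) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (size - 1) / 2;
  int m = size * size * size;
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> buf(m);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int p = 0;
        for (int dz = -r; dz <= r; ++dz) {
          int zi = clampi(z + dz, nz);
          for (int dy = -r; dy <= r; ++dy) {
            int yi = clampi(y + dy, ny);
            for (int dx = -r; dx <= r; ++dx) {
              int xi = clampi(x + dx, nx);
              buf[p++] = img[xi + (size_t)nx * (yi + (size_t)ny * zi)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        out[x + (size_t)nx * (y + (size_t)ny * z)] = buf[m / 2];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Exhaustive normalized cross-correlation score map. The template is slid to
// every integer offset (x,y,z) with 0 <= x <= nx-lx etc.; the score is the
// mean of standardized products over the overlap (population SDs on both
// sides). Windows with (numerically) zero variance get the sentinel -2, which
// can never win the argmax against any genuine correlation.
// [[Rcpp::export]]
NumericVector cpp_ncc_map(NumericVector img, IntegerVector idim,
                          NumericVector tpl, IntegerVector tdim) {
  int nx = idim[0], ny = idim[1], nz = idim[2];
  int lx = tdim[0], ly = tdim[1], lz = tdim[2];
  int ox = nx - lx + 1, oy = ny - ly + 1, oz = nz - lz + 1;
  double m = (double)lx * ly * lz;

  double tmean = 0.0;
  for (int i = 0; i < (int)m; ++i) tmean += tpl[i];
  tmean /= m;
  double tvar = 0.0;
  for (int i = 0; i < (int)m; ++i) {
    double d = tpl[i] - tmean;
    tvar += d * d;
  }
  tvar /= m;
  double tsd = std::sqrt(tvar);
  if (tsd <= 0.0) stop("template has zero variance");

  NumericVector out((size_t)ox * oy * oz);
  const double *f = img.begin();
  const double *t = tpl.begin();
  for (int z = 0; z < oz; ++z) {
    for (int y = 0; y < oy; ++y) {
      for (int x = 0; x < ox; ++x) {
        double sf = 0.0, sff = 0.0, sft = 0.0;
        for (int k = 0; k < lz; ++k) {
          for (int j = 0; j < ly; ++j) {
            const double *frow =
                f + (size_t)(x) + (size_t)nx * ((y + j) + (size_t)ny * (z + k));
            const double *trow = t + (size_t)lx * (j + (size_t)ly * k);
            for (int i = 0; i < lx; ++i) {
              double v = frow[i];
              sf += v;
              sff += v * v;
              sft += v * trow[i];
            }
          }
        }
        double fmean = sf / m;
        double fvar = sff / m - fmean * fmean;
        double score;
        if (fvar <= 1e-12 * (std::abs(sff / m) + 1e-30) || fvar <= 0.0) {
          score = -2.0;
        } else {
          double cov = sft / m - fmean * tmean;
          score = cov / (std::sqrt(fvar) * tsd);
        }
        out[x + (size_t)ox * (y + (size_t)oy * z)] = score;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Eigenvalues of the symmetric 3x3 matrix [[xx,xy,xz],[xy,yy,yz],[xz,yz,zz]]
// per voxel, by the trigonometric (Smith) method; returned sorted so that
// l1 >= l2 >= l3.
// [[Rcpp::export]]
List cpp_eig3sym(NumericVector xx, NumericVector yy, NumericVector zz,
                 NumericVector xy, NumericVector xz, NumericVector yz) {
  R_xlen_t n = xx.size();
  NumericVector l1(n), l2(n), l3(n);
  const double twopi3 = 2.0 * M_PI / 3.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = xx[i], b = yy[i], c = zz[i];
    double d = xy[i], e = yz[i], f = xz[i];
    double q = (a + b + c) / 3.0;
    double aa = a - q, bb = b - q, cc = c - q;
    double p2 = (aa * aa + bb * bb + cc * cc) / 6.0 +
                (d * d + e * e + f * f) / 3.0;
    double p = std::sqrt(p2);
    double e1, e2, e3;
    if (p < 1e-300) {
      e1 = e2 = e3 = q;
    } else {
      // det of (A - qI) / p
      double m00 = aa / p, m11 = bb / p, m22 = cc / p;
      double m01 = d / p, m12 = e / p, m02 = f / p;
      double det = m00 * (m11 * m22 - m12 * m12) -
                   m01 * (m01 * m22 - m12 * m02) +
                   m02 * (m01 * m12 - m11 * m02);
      double r = det / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + twopi3);
      e2 = 3.0 * q - e1 - e3;
    }
    l1[i] = e1;
    l2[i] = e2;
    l3[i] = e3;
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

static inline double keys_w(double t) {
  // Keys cubic convolution kernel, a = -0.5
  double at = std::abs(t);
  if (at < 1.0) return ((1.5 * at - 2.5) * at) * at + 1.0;
  if (at < 2.0) return (((-0.5 * at + 2.5) * at) - 4.0) * at + 2.0;
  return 0.0;
}

// Resample: output voxel (i,j,k) samples the input at continuous input-index
// coordinates off[a] + i * sc[a] along axis a. method: 0 trilinear, 1 Keys
// tricubic. Out-of-range taps are edge-clamped.
// [[Rcpp::export]]
NumericVector cpp_resample3(NumericVector img, IntegerVector dim,
                            IntegerVector odim, NumericVector sc,
                            NumericVector off, int method) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *f = img.begin();

  for (int k = 0; k < oz; ++k) {
    double pz = off[2] + k * sc[2];
    for (int j = 0; j < oy; ++j) {
      double py = off[1] + j * sc[1];
      for (int i = 0; i < ox; ++i) {
        double px = off[0] + i * sc[0];
        double val;
        if (method == 0) {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            double wz = dz ? fz : 1.0 - fz;
            int zi = clampi(z0 + dz, nz);
            for (int dy = 0; dy <= 1; ++dy) {
              double wy = dy ? fy : 1.0 - fy;
              int yi = clampi(y0 + dy, ny);
              for (int dx = 0; dx <= 1; ++dx) {
                double wx = dx ? fx : 1.0 - fx;
                int xi = clampi(x0 + dx, nx);
                acc += wx * wy * wz *
                       f[xi + (size_t)nx * (yi + (size_t)ny * zi)];
              }
            }
          }
          val = acc;
        } else {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double wxs[4], wys[4], wzs[4];
          for (int u = 0; u < 4; ++u) {
            wxs[u] = keys_w(px - (x0 - 1 + u));
            wys[u] = keys_w(py - (y0 - 1 + u));
            wzs[u] = keys_w(pz - (z0 - 1 + u));
          }
          double acc = 0.0;
          for (int dz = 0; dz < 4; ++dz) {
            int zi = clampi(z0 - 1 + dz, nz);
            double wz = wzs[dz];
            if (wz == 0.0) continue;
            for (int dy = 0; dy < 4; ++dy) {
              int yi = clampi(y0 - 1 + dy, ny);
              double wyz = wys[dy] * wz;
              if (wyz == 0.0) continue;
              size_t base = (size_t)nx * (yi + (size_t)ny * zi);
              for (int dx = 0; dx < 4; ++dx) {
                int xi = clampi(x0 - 1 + dx, nx);
                acc += wxs[dx] * wyz * f[xi + base];
              }
            }
          }
          val = acc;
        }
        out[i + (size_t)ox * (j + (size_t)oy * k)] = val;
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}
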