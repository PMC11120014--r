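#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution kernels for volumetric networks.
// Array layouts follow R column-major convention:
//   activations x : (X, Y, Z, C_in, N)
//   weights     w : (K, K, K, C_in, C_out)
//   output      y : (Xo, Yo, Zo, C_out, N)

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// valid output range [lo, hi] such that 0 <= o*stride - pad + koff < in
static inline void valid_range(int in, int n_out, int stride, int pad, int koff,
                               int &lo, int &hi) {
  int a = pad - koff;
  lo = (a > 0) ? (a + stride - 1) / stride : 0;
  int b = in - 1 + pad - koff;
  hi = (b < 0) ? -1 : b / stride;
  if (hi > n_out - 1) hi = n_out - 1;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  if (wd[3] != Ci) stop("weight C_in does not match input channels");
  const int Xo = out_extent(X, K, stride, pad);
  const int Yo = out_extent(Y, K, stride, pad);
  const int Zo = out_extent(Z, K, stride, pad);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("input too small for kernel/stride/pad");

  NumericVector y(R_xlen_t(Xo) * Yo * Zo * Co * N);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co, N);
  double *yp = REAL(y);
  const double *xp = REAL(x), *wp = REAL(w), *bp = REAL(b);

  const R_xlen_t xyz = R_xlen_t(X) * Y * Z;
  const R_xlen_t oxyz = R_xlen_t(Xo) * Yo * Zo;

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double *ys = yp + oxyz * (co + R_xlen_t(Co) * n);
      const double bv = bp[co];
      for (R_xlen_t i = 0; i < oxyz; ++i) ys[i] = bv;
    }

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double *ys = yp + oxyz * (co + R_xlen_t(Co) * n);
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xs = xp + xyz * (ci + R_xlen_t(Ci) * n);
        const double *ws = wp + R_xlen_t(K) * K * K * (ci + R_xlen_t(Ci) * co);
        for (int kz = 0; kz < K; ++kz) {
          int zlo, zhi; valid_range(Z, Zo, stride, pad, kz, zlo, zhi);
          for (int ky = 0; ky < K; ++ky) {
            int ylo, yhi; valid_range(Y, Yo, stride, pad, ky, ylo, yhi);
            for (int kx = 0; kx < K; ++kx) {
              int xlo, xhi; valid_range(X, Xo, stride, pad, kx, xlo, xhi);
              const double wv = ws[kx + K * (ky + K * kz)];
              if (wv == 0.0) continue;
              for (int zo = zlo; zo <= zhi; ++zo) {
                const int z = zo * stride - pad + kz;
                for (int yo = ylo; yo <= yhi; ++yo) {
                  const int yy = yo * stride - pad + ky;
                  const double *xr = xs + X * (R_xlen_t(yy) + Y * z);
                  double *yr = ys + Xo * (R_xlen_t(yo) + Yo * zo);
                  int xi = xlo * stride - pad + kx;
                  for (int xo = xlo; xo <= xhi; ++xo, xi += stride)
                    yr[xo] += wv * xr[xi];
                }
              }
            }
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2];

  NumericVector dx(R_xlen_t(X) * Y * Z * Ci * N);
  dx.attr("dim") = xd;
  NumericVector dw(R_xlen_t(K) * K * K * Ci * Co);
  dw.attr("dim") = wd;
  NumericVector db(Co);

  double *dxp = REAL(dx), *dwp = REAL(dw), *dbp = REAL(db);
  const double *xp = REAL(x), *wp = REAL(w), *dyp = REAL(dy);
  const R_xlen_t xyz = R_xlen_t(X) * Y * Z;
  const R_xlen_t oxyz = R_xlen_t(Xo) * Yo * Zo;

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double *dys = dyp + oxyz * (co + R_xlen_t(Co) * n);
      double acc = 0.0;
      for (R_xlen_t i = 0; i < oxyz; ++i) acc += dys[i];
      dbp[co] += acc;
    }

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double *dys = dyp + oxyz * (co + R_xlen_t(Co) * n);
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xs = xp + xyz * (ci + R_xlen_t(Ci) * n);
        double *dxs = dxp + xyz * (ci + R_xlen_t(Ci) * n);
        const double *ws = wp + R_xlen_t(K) * K * K * (ci + R_xlen_t(Ci) * co);
        double *dws = dwp + R_xlen_t(K) * K * K * (ci + R_xlen_t(Ci) * co);
        for (int kz = 0; kz < K; ++kz) {
          int zlo, zhi; valid_range(Z, Zo, stride, pad, kz, zlo, zhi);
          for (int ky = 0; ky < K; ++ky) {
            int ylo, yhi; valid_range(Y, Yo, stride, pad, ky, ylo, yhi);
            for (int kx = 0; kx < K; ++kx) {
              int xlo, xhi; valid_range(X, Xo, stride, pad, kx, xlo, xhi);
              const double wv = ws[kx + K * (ky + K * kz)];
              double wg = 0.0;
              for (int zo = zlo; zo <= zhi; ++zo) {
                const int z = zo * stride - pad + kz;
                for (int yo = ylo; yo <= yhi; ++yo) {
                  const int yy = yo * stride - pad + ky;
                  const double *xr = xs + X * (R_xlen_t(yy) + Y * z);
                  double *dxr = dxs + X * (R_xlen_t(yy) + Y * z);
                  const double *dyr = dys + Xo * (R_xlen_t(yo) + Yo * zo);
                  int xi = xlo * stride - pad + kx;
                  for (int xo = xlo; xo <= xhi; ++xo, xi += stride) {
                    const double g = dyr[xo];
                    wg += g * xr[xi];
                    dxr[xi] += wv * g;
                  }
                }
              }
              dws[kx + K * (ky + K * kz)] += wg;
            }
          }
        }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// trilinear sampling at continuous 0-based coordinates, edge-replicated
static inline double sample_trilinear(const double *xp, int X, int Y, int Z,
                                      double sx, double sy, double sz) {
  sx = clampd(sx, 0.0, X - 1.0);
  sy = clampd(sy, 0.0, Y - 1.0);
  sz = clampd(sz, 0.0, Z - 1.0);
  const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
            z1 = std::min(z0 + 1, Z - 1);
  const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  #define V(i, j, k) xp[(i) + X * (R_xlen_t(j) + Y * (k))]
  const double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  const double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  const double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  const double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector resize_trilinear_cpp(NumericVector x, IntegerVector out_dim) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector y(R_xlen_t(Xo) * Yo * Zo);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  double *yp = REAL(y);
  const double *xp = REAL(x);
  const double rx = double(X) / Xo, ry = double(Y) / Yo, rz = double(Z) / Zo;
  R_xlen_t idx = 0;
  for (int k = 0; k < Zo; ++k) {
    const double sz = (k + 0.5) * rz - 0.5;
    for (int j = 0; j < Yo; ++j) {
      const double sy = (j + 0.5) * ry - 0.5;
      for (int i = 0; i < Xo; ++i, ++idx) {
        const double sx = (i + 0.5) * rx - 0.5;
        yp[idx] = sample_trilinear(xp, X, Y, Z, sx, sy, sz);
      }
    }
  }
  return y;
}

// Apply an affine map to a single-channel volume. M is 3x4; an output voxel
// at 0-based (i,j,k) samples the input at M %*% c(i,j,k,1).
// [[Rcpp::export]]
NumericVector affine_warp_cpp(NumericVector x, NumericMatrix M) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  NumericVector y(R_xlen_t(X) * Y * Z);
  y.attr("dim") = xd;
  double *yp = REAL(y);
  const double *xp = REAL(x);
  R_xlen_t idx = 0;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i, ++idx) {
        const double sx = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + M(0, 3);
        const double sy = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + M(1, 3);
        const double sz = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + M(2, 3);
        yp[idx] = sample_trilinear(xp, X, Y, Z, sx, sy, sz);
      }
  return y;
}
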