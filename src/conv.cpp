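// Convolution primitives for the denoiser architectures.
//
// Feature maps are dense double arrays in R's column-major layout:
//   2D: (H, W, C, N)      -- row (y) fastest
//   3D: (D, H, W, C, N)   -- depth (z) fastest
// Kernels:
//   2D: (k, k, Cin, Cout), 3D: (k, k, k, Cin, Cout), k odd, "same" zero padding.
//
// The general path is chunked im2col + BLAS gemm; a direct loop path handles
// the single-channel case (the affine model's one 31x31 filter) where im2col
// buffers would be pure memory traffic.

#include <RcppArmadillo.h>
#include <cstring>
#include <vector>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static const size_t CHUNK_DOUBLES = 20000000; // ~160 MB im2col buffer cap

// ---------------------------------------------------------------- 2D helpers

// Fill out (m x k*k*C, leading dim m) with input patches for output pixels
// [p0, p1) of one image, pixel order p = y + H*x.
static void im2col2d(const double* x, int H, int W, int C, int k, int pad,
                     int p0, int p1, double* out) {
  const int m = p1 - p0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kx = 0; kx < k; ++kx) {
      const int sx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int sy = ky - pad;
        double* col = out + (size_t)m * (ky + k * kx + (size_t)k * k * c);
        int p = p0;
        while (p < p1) {
          const int w0 = p / H, h0 = p % H;
          const int hend = std::min(H, h0 + (p1 - p));
          const int wi = w0 + sx;
          double* dst = col + (p - p0);
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + (hend - h0), 0.0);
          } else {
            const double* src = xc + (size_t)H * wi;
            const int vh0 = std::max(h0, -sy), vh1 = std::min(hend, H - sy);
            if (vh1 <= vh0) {
              std::fill(dst, dst + (hend - h0), 0.0);
            } else {
              if (vh0 > h0) std::fill(dst, dst + (vh0 - h0), 0.0);
              std::memcpy(dst + (vh0 - h0), src + vh0 + sy,
                          sizeof(double) * (vh1 - vh0));
              if (hend > vh1) std::fill(dst + (vh1 - h0), dst + (hend - h0), 0.0);
            }
          }
          p += hend - h0;
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient (m x k*k*C) back onto dx.
static void col2im_add2d(const double* cols, int H, int W, int C, int k,
                         int pad, int p0, int p1, double* dx) {
  const int m = p1 - p0;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kx = 0; kx < k; ++kx) {
      const int sx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int sy = ky - pad;
        const double* col = cols + (size_t)m * (ky + k * kx + (size_t)k * k * c);
        int p = p0;
        while (p < p1) {
          const int w0 = p / H, h0 = p % H;
          const int hend = std::min(H, h0 + (p1 - p));
          const int wi = w0 + sx;
          if (wi >= 0 && wi < W) {
            const int vh0 = std::max(h0, -sy), vh1 = std::min(hend, H - sy);
            if (vh1 > vh0) {
              const double* src = col + (p - p0) + (vh0 - h0);
              double* dst = xc + (size_t)H * wi + vh0 + sy;
              const int len = vh1 - vh0;
              for (int h = 0; h < len; ++h) dst[h] += src[h];
            }
          }
          p += hend - h0;
        }
      }
    }
  }
}

static int chunk_rows(size_t npix, int K) {
  size_t c = CHUNK_DOUBLES / (size_t)std::max(1, K);
  c = std::max<size_t>(c, 1024);
  return (int)std::min(npix, c);
}

// ------------------------------------------------------------ 2D single-chan
// Direct convolution when Cin == Cout == 1 (the affine architecture).

static void conv1_fw2d(const double* x, const double* w, double b, int H,
                       int W, int k, int pad, double* y) {
  const size_t npix = (size_t)H * W;
  for (size_t i = 0; i < npix; ++i) y[i] = b;
  for (int kx = 0; kx < k; ++kx) {
    const int sx = kx - pad;
    for (int ky = 0; ky < k; ++ky) {
      const int sy = ky - pad;
      const double wv = w[ky + k * kx];
      if (wv == 0.0) continue;
      const int w0 = std::max(0, -sx), w1 = std::min(W, W - sx);
      const int h0 = std::max(0, -sy), h1 = std::min(H, H - sy);
      for (int wc = w0; wc < w1; ++wc) {
        double* yc = y + (size_t)H * wc;
        const double* xc = x + (size_t)H * (wc + sx) + sy;
        for (int h = h0; h < h1; ++h) yc[h] += wv * xc[h];
      }
    }
  }
}

static void conv1_bw2d(const double* x, const double* w, const double* dy,
                       int H, int W, int k, int pad, double* dx, double* dw,
                       double* db, bool need_dx) {
  const size_t npix = (size_t)H * W;
  for (size_t i = 0; i < npix; ++i) *db += dy[i];
  for (int kx = 0; kx < k; ++kx) {
    const int sx = kx - pad;
    for (int ky = 0; ky < k; ++ky) {
      const int sy = ky - pad;
      const double wv = w[ky + k * kx];
      double acc = 0.0;
      const int w0 = std::max(0, -sx), w1 = std::min(W, W - sx);
      const int h0 = std::max(0, -sy), h1 = std::min(H, H - sy);
      for (int wc = w0; wc < w1; ++wc) {
        const double* dyc = dy + (size_t)H * wc;
        const double* xc = x + (size_t)H * (wc + sx) + sy;
        double* dxc = dx + (size_t)H * (wc + sx) + sy;
        if (need_dx) {
          for (int h = h0; h < h1; ++h) {
            acc += dyc[h] * xc[h];
            dxc[h] += wv * dyc[h];
          }
        } else {
          for (int h = h0; h < h1; ++h) acc += dyc[h] * xc[h];
        }
      }
      dw[ky + k * kx] += acc;
    }
  }
}

// ------------------------------------------------------------------- exports

// Shifted-view dgemm 2D convolution ("implicit gemm"): for each kernel
// offset, one big gemm on row-shifted views of the (npix x C) pixel-major
// matrices, followed by cheap corrections for the rows where the row shift
// wraps across image columns (those contributions must be zero padding).

static void offset_range(int r, size_t npix, int* r0, int* r1) {
  *r0 = std::max(0, -r);
  *r1 = (int)npix - std::max(0, r);
}

// bad output rows p in [r0,r1): (p % H) + sy outside [0, H)
template <typename F>
static void for_bad_rows(int H, int W, int sy, int r0, int r1, F fn) {
  if (sy == 0) return;
  for (int w = 0; w < W; ++w) {
    int hlo = (sy < 0) ? 0 : H - sy;
    int hhi = (sy < 0) ? -sy : H;
    for (int h = hlo; h < hhi; ++h) {
      int p = h + H * w;
      if (p >= r0 && p < r1) fn(p);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  const size_t npix = (size_t)H * W;
  NumericVector y((R_xlen_t)(npix * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  if (C == 1) {  // direct path: input plane stays in cache
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co)
        conv1_fw2d(x.begin() + npix * n, w.begin() + (size_t)k * k * co,
                   b[co], H, W, k, pad, y.begin() + npix * Cout * n + npix * co);
    return y;
  }

  const int ione = 1;
  std::vector<double> Wb((size_t)C * Cout);
  for (int n = 0; n < N; ++n) {
    const double* X = x.begin() + npix * C * n;
    double* Y = y.begin() + npix * Cout * n;
    for (int co = 0; co < Cout; ++co)
      std::fill(Y + npix * co, Y + npix * (co + 1), b[co]);
    for (int kx = 0; kx < k; ++kx) {
      const int sx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int sy = ky - pad;
        const int r = sy + H * sx;
        int r0, r1;
        offset_range(r, npix, &r0, &r1);
        // clip horizontally impossible columns via row range only; rows whose
        // intended column is out of bounds are already outside [r0, r1)
        if (r1 <= r0) continue;
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wb[ci + (size_t)C * co] =
              w[ky + k * kx + (size_t)k * k * (ci + (size_t)C * co)];
        const int m = r1 - r0;
        const double one = 1.0;
        const int ldx = (int)npix;
        F77_CALL(dgemm)("N", "N", &m, &Cout, const_cast<int*>(&C), &one,
                        const_cast<double*>(X) + r0 + r, &ldx, Wb.data(),
                        const_cast<int*>(&C), &one, Y + r0, &ldx
                        FCONE FCONE);
        for_bad_rows(H, W, sy, r0, r1, [&](int p) {
          for (int co = 0; co < Cout; ++co) {
            double acc = 0.0;
            for (int ci = 0; ci < C; ++ci)
              acc += X[p + r + npix * ci] * Wb[ci + (size_t)C * co];
            Y[p + npix * co] -= acc;
          }
        });
        (void)ione;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  const size_t npix = (size_t)H * W;
  NumericVector dx((R_xlen_t)(npix * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)((size_t)k * k * C * Cout));
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  if (C == 1) {
    for (int n = 0; n < N; ++n) {
      double db0 = 0.0;
      for (int co = 0; co < Cout; ++co) {
        db0 = 0.0;
        conv1_bw2d(x.begin() + npix * n, w.begin() + (size_t)k * k * co,
                   dy.begin() + npix * Cout * n + npix * co, H, W, k, pad,
                   dx.begin() + npix * n, dw.begin() + (size_t)k * k * co,
                   &db0, need_dx);
        db[co] += db0;
      }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  std::vector<double> Wb((size_t)C * Cout), dWb((size_t)C * Cout);
  for (int n = 0; n < N; ++n) {
    const double* X = x.begin() + npix * C * n;
    const double* D = dy.begin() + npix * Cout * n;
    double* dX = dx.begin() + npix * C * n;
    for (int kx = 0; kx < k; ++kx) {
      const int sx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int sy = ky - pad;
        const int r = sy + H * sx;
        int r0, r1;
        offset_range(r, npix, &r0, &r1);
        if (r1 <= r0) continue;
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wb[ci + (size_t)C * co] =
              w[ky + k * kx + (size_t)k * k * (ci + (size_t)C * co)];
        std::fill(dWb.begin(), dWb.end(), 0.0);
        const int m = r1 - r0;
        const double one = 1.0, zero = 0.0;
        const int ldx = (int)npix;
        // dWb (C x Cout) = X_shift^T * D
        F77_CALL(dgemm)("T", "N", const_cast<int*>(&C), &Cout, &m, &one,
                        const_cast<double*>(X) + r0 + r, &ldx,
                        const_cast<double*>(D) + r0, &ldx, &zero, dWb.data(),
                        const_cast<int*>(&C) FCONE FCONE);
        for_bad_rows(H, W, sy, r0, r1, [&](int p) {
          for (int co = 0; co < Cout; ++co)
            for (int ci = 0; ci < C; ++ci)
              dWb[ci + (size_t)C * co] -= X[p + r + npix * ci] *
                D[p + npix * co];
        });
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            dw[ky + k * kx + (size_t)k * k * (ci + (size_t)C * co)] +=
              dWb[ci + (size_t)C * co];
        if (need_dx) {
          // dX_shift += D * Wb^T
          F77_CALL(dgemm)("N", "T", &m, const_cast<int*>(&C), &Cout, &one,
                          const_cast<double*>(D) + r0, &ldx, Wb.data(),
                          const_cast<int*>(&C), &one, dX + r0 + r, &ldx
                          FCONE FCONE);
          for_bad_rows(H, W, sy, r0, r1, [&](int p) {
            for (int ci = 0; ci < C; ++ci) {
              double acc = 0.0;
              for (int co = 0; co < Cout; ++co)
                acc += D[p + npix * co] * Wb[ci + (size_t)C * co];
              dX[p + r + npix * ci] -= acc;
            }
          });
        }
      }
    }
  }
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* src = dy.begin() + npix * Cout * n + npix * co;
      for (size_t i = 0; i < npix; ++i) acc += src[i];
    }
    db[co] = acc;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------- 3D helpers

// Pixel order p = z + D*(y + H*x); columns j = kz + k*ky + k^2*kx + k^3*c.
static void im2col3d(const double* x, int D, int H, int W, int C, int k,
                     int pad, int p0, int p1, double* out) {
  const int m = p1 - p0;
  const size_t nvox = (size_t)D * H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + nvox * c;
    for (int kx = 0; kx < k; ++kx) {
      const int sx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int sy = ky - pad;
        for (int kz = 0; kz < k; ++kz) {
          const int sz = kz - pad;
          double* col = out + (size_t)m * (kz + k * ky + (size_t)k * k * kx +
                                           (size_t)k * k * k * c);
          int p = p0;
          while (p < p1) {
            const int w0 = p / (D * H);
            const int rem = p % (D * H);
            const int h0 = rem / D, d0 = rem % D;
            const int dend = std::min(D, d0 + (p1 - p));
            const int wi = w0 + sx, hi = h0 + sy;
            double* dst = col + (p - p0);
            if (wi < 0 || wi >= W || hi < 0 || hi >= H) {
              std::fill(dst, dst + (dend - d0), 0.0);
            } else {
              const double* src = xc + (size_t)D * (hi + (size_t)H * wi);
              const int vd0 = std::max(d0, -sz), vd1 = std::min(dend, D - sz);
              if (vd1 <= vd0) {
                std::fill(dst, dst + (dend - d0), 0.0);
              } else {
                if (vd0 > d0) std::fill(dst, dst + (vd0 - d0), 0.0);
                std::memcpy(dst + (vd0 - d0), src + vd0 + sz,
                            sizeof(double) * (vd1 - vd0));
                if (dend > vd1) std::fill(dst + (vd1 - d0), dst + (dend - d0), 0.0);
              }
            }
            p += dend - d0;
          }
        }
      }
    }
  }
}

static void col2im_add3d(const double* cols, int D, int H, int W, int C, int k,
                         int pad, int p0, int p1, double* dx) {
  const int m = p1 - p0;
  const size_t nvox = (size_t)D * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + nvox * c;
    for (int kx = 0; kx < k; ++kx) {
      const int sx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int sy = ky - pad;
        for (int kz = 0; kz < k; ++kz) {
          const int sz = kz - pad;
          const double* col = cols + (size_t)m * (kz + k * ky +
                              (size_t)k * k * kx + (size_t)k * k * k * c);
          int p = p0;
          while (p < p1) {
            const int w0 = p / (D * H);
            const int rem = p % (D * H);
            const int h0 = rem / D, d0 = rem % D;
            const int dend = std::min(D, d0 + (p1 - p));
            const int wi = w0 + sx, hi = h0 + sy;
            if (wi >= 0 && wi < W && hi >= 0 && hi < H) {
              const int vd0 = std::max(d0, -sz), vd1 = std::min(dend, D - sz);
              if (vd1 > vd0) {
                const double* src = col + (p - p0) + (vd0 - d0);
                double* dst = xc + (size_t)D * (hi + (size_t)H * wi) + vd0 + sz;
                const int len = vd1 - vd0;
                for (int d = 0; d < len; ++d) dst[d] += src[d];
              }
            }
            p += dend - d0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  const int pad = (k - 1) / 2, K = k * k * k * C;
  const size_t nvox = (size_t)D * H * W;
  NumericVector y((R_xlen_t)(nvox * Cout * N));
  y.attr("dim") = IntegerVector::create(D, H, W, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  const int chunk = chunk_rows(nvox, K);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + nvox * C * n;
    double* yn = y.begin() + nvox * Cout * n;
    for (int p0 = 0; p0 < (int)nvox; p0 += chunk) {
      const int p1 = std::min((int)nvox, p0 + chunk), m = p1 - p0;
      arma::mat Cm(m, K);
      im2col3d(xn, D, H, W, C, k, pad, p0, p1, Cm.memptr());
      arma::mat Ym = Cm * Wm;
      for (int co = 0; co < Cout; ++co) {
        double* dst = yn + nvox * co + p0;
        const double* src = Ym.colptr(co);
        const double bc = b[co];
        for (int r = 0; r < m; ++r) dst[r] = src[r] + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  const int pad = (k - 1) / 2, K = k * k * k * C;
  const size_t nvox = (size_t)D * H * W;
  NumericVector dx((R_xlen_t)(nvox * C * N));
  dx.attr("dim") = IntegerVector::create(D, H, W, C, N);
  NumericVector dw((R_xlen_t)((size_t)K * Cout));
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  const int chunk = chunk_rows(nvox, K);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + nvox * C * n;
    const double* dyn = dy.begin() + nvox * Cout * n;
    double* dxn = dx.begin() + nvox * C * n;
    for (int p0 = 0; p0 < (int)nvox; p0 += chunk) {
      const int p1 = std::min((int)nvox, p0 + chunk), m = p1 - p0;
      arma::mat Cm(m, K);
      im2col3d(xn, D, H, W, C, k, pad, p0, p1, Cm.memptr());
      arma::mat Dm(m, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* src = dyn + nvox * co + p0;
        std::copy(src, src + m, Dm.colptr(co));
      }
      dWm += Cm.t() * Dm;
      if (need_dx) {
        arma::mat Gm = Dm * Wm.t();
        col2im_add3d(Gm.memptr(), D, H, W, C, k, pad, p0, p1, dxn);
      }
    }
  }
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* src = dy.begin() + nvox * Cout * n + nvox * co;
      for (size_t i = 0; i < nvox; ++i) acc += src[i];
    }
    db[co] = acc;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------------------ pointwise ops

// [[Rcpp::export]]
NumericVector cpp_lrelu_fw(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yi[i] = xi[i] > 0 ? xi[i] : slope * xi[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bw(NumericVector x, NumericVector dy, double slope) {
  NumericVector g(x.size());
  g.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  const double* di = dy.begin();
  double* gi = g.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    gi[i] = xi[i] > 0 ? di[i] : slope * di[i];
  return g;
}
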