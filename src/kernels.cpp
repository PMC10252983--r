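// Numerical kernels: separable filtering with reflective borders and the
// convolution/pooling/resampling primitives (forward + backward) behind the
// segmentation network. Feature volumes are stored as R arrays [H, W, C, N]
// (column-major), weights as [k, k, Cin, Cout].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// symmetric (half-sample) reflection: ... 2 1 0 | 0 1 2 ... | n-1 n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// whole-sample reflection (reflect-101): ... 2 1 | 0 1 2 ... | n-2 n-3 ...
// preserves even/odd parity, which the pyramid Expand needs so that the
// zero-inserted sample grid reflects onto itself
static inline int reflect101_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - i);
}

// [[Rcpp::export]]
NumericMatrix cpp_sepconv_reflect(NumericMatrix x, NumericVector kernel,
                                  bool whole_sample = false) {
  const int H = x.nrow(), W = x.ncol(), K = kernel.size();
  const int r = (K - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = 0; t < K; ++t) {
        int ii = whole_sample ? reflect101_idx(i + t - r, H)
                              : reflect_idx(i + t - r, H);
        acc += kernel[t] * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  // horizontal pass
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = 0; t < K; ++t) {
        int jj = whole_sample ? reflect101_idx(j + t - r, W)
                              : reflect_idx(j + t - r, W);
        acc += kernel[t] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// ---- im2col convolution, stride 1, zero padding p = (k-1)/2 (same size) ----

static void im2col_fill(const double* xp, int H, int W, int Ci, int k, int p,
                        arma::mat& M) {
  // M: (H*W) x (k*k*Ci); column r = ky + k*kx + k*k*ci holds the patch value
  // at offset (ky, kx) of channel ci, zero outside the image.
  M.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const double* plane = xp + (size_t)ci * H * W;
    for (int kx = 0; kx < k; ++kx) {
      int dj = kx - p;
      int j0 = std::max(0, -dj), j1 = std::min(W, W - dj); // out cols with valid src
      for (int ky = 0; ky < k; ++ky) {
        int di = ky - p;
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        double* col = M.colptr(ky + k * kx + k * k * ci);
        for (int j = j0; j < j1; ++j) {
          const double* src = plane + (size_t)(j + dj) * H + (i0 + di);
          double* dst = col + (size_t)j * H + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& G, int H, int W, int Ci, int k, int p,
                       double* xp) {
  for (int ci = 0; ci < Ci; ++ci) {
    double* plane = xp + (size_t)ci * H * W;
    for (int kx = 0; kx < k; ++kx) {
      int dj = kx - p;
      int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      for (int ky = 0; ky < k; ++ky) {
        int di = ky - p;
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const double* col = G.colptr(ky + k * kx + k * k * ci);
        for (int j = j0; j < j1; ++j) {
          double* dst = plane + (size_t)(j + dj) * H + (i0 + di);
          const double* src = col + (size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// batch-stacked im2col: rows of M are grouped per sample, so one GEMM covers
// the whole mini-batch
static void im2col_fill_batch(const double* xp, int H, int W, int Ci, int N,
                              int k, int p, arma::mat& M) {
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < Ci; ++ci) {
      const double* plane = xp + ((size_t)n * Ci + ci) * HW;
      for (int kx = 0; kx < k; ++kx) {
        int dj = kx - p;
        int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int ky = 0; ky < k; ++ky) {
          int di = ky - p;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double* col = M.colptr(ky + k * kx + k * k * ci) + (size_t)n * HW;
          for (int j = j0; j < j1; ++j) {
            const double* src = plane + (size_t)(j + dj) * H + (i0 + di);
            double* dst = col + (size_t)j * H + i0;
            std::copy(src, src + (i1 - i0), dst);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int k = wdim[0], Co = wdim[3];
  const int p = (k - 1) / 2;
  const int HW = H * W;
  const arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Ci, Co, false);
  NumericVector y((size_t)HW * Co * N);
  arma::mat M((size_t)HW * N, k * k * Ci, arma::fill::zeros);
  im2col_fill_batch(x.begin(), H, W, Ci, N, k, p, M);
  arma::mat Y = M * Wmat; // (N*HW) x Co
  const bool has_b = bias.size() == Co;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* src = Y.colptr(co) + (size_t)n * HW;
      double* dst = y.begin() + ((size_t)n * Co + co) * HW;
      if (has_b) {
        double bv = bias[co];
        for (int i = 0; i < HW; ++i) dst[i] = src[i] + bv;
      } else {
        std::copy(src, src + HW, dst);
      }
    }
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy, bool need_dx, bool has_bias) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int k = wdim[0], Co = wdim[3];
  const int p = (k - 1) / 2;
  const int HW = H * W;
  const arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Ci, Co, false);
  arma::vec db(Co, arma::fill::zeros);
  NumericVector dx(need_dx ? (size_t)HW * Ci * N : 0);
  arma::mat M((size_t)HW * N, k * k * Ci, arma::fill::zeros);
  im2col_fill_batch(x.begin(), H, W, Ci, N, k, p, M);
  // restack dy into (N*HW) x Co
  arma::mat dY((size_t)HW * N, Co);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* src = dy.begin() + ((size_t)n * Co + co) * HW;
      std::copy(src, src + HW, dY.colptr(co) + (size_t)n * HW);
    }
  arma::mat dW = M.t() * dY;
  if (has_bias) db = arma::sum(dY, 0).t();
  if (need_dx) {
    arma::mat G = dY * Wmat.t(); // (N*HW) x kkCi
    for (int n = 0; n < N; ++n) {
      arma::mat Gn = G.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1);
      col2im_add(Gn, H, W, Ci, k, p, dx.begin() + (size_t)n * HW * Ci);
    }
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wdim;
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dw"] = dwv, _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// ---- 2x2 max pooling, stride 2 ----

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0..3 = (di,dj) in column-major
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int bi = 2 * i, bj = 2 * j;
          double best = plane[(size_t)bj * H + bi];
          int arg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = plane[(size_t)(bj + dj) * H + bi + di];
              if (v > best) { best = v; arg = di + 2 * dj; }
            }
          y[q] = best; idx[q] = arg; ++q;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * C * N);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int arg = idx[q];
          int di = arg % 2, dj = arg / 2;
          plane[(size_t)(2 * j + dj) * H + 2 * i + di] += dy[q];
          ++q;
        }
    }
  dx.attr("dim") = xdim;
  return dx;
}

// ---- bilinear resampling (used as x2 upsampling and its adjoint) ----

static void bilin_axis(int nin, int nout, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(nout); i1.resize(nout); w1.resize(nout);
  for (int i = 0; i < nout; ++i) {
    double s = (i + 0.5) * (double)nin / nout - 0.5;
    if (s < 0) s = 0;
    if (s > nin - 1) s = nin - 1;
    int a = (int)std::floor(s);
    int b = std::min(a + 1, nin - 1);
    i0[i] = a; i1[i] = b; w1[i] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bilinear_fwd(NumericVector x, IntegerVector xdim,
                                        int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  bilin_axis(H, Ho, ri0, ri1, rw);
  bilin_axis(W, Wo, cj0, cj1, cw);
  NumericVector y((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + ((size_t)n * C + c) * H * W;
      double* dst = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        const double* s0 = src + (size_t)cj0[j] * H;
        const double* s1 = src + (size_t)cj1[j] * H;
        double wj = cw[j];
        for (int i = 0; i < Ho; ++i) {
          double a = s0[ri0[i]] * (1 - rw[i]) + s0[ri1[i]] * rw[i];
          double b = s1[ri0[i]] * (1 - rw[i]) + s1[ri1[i]] * rw[i];
          dst[(size_t)j * Ho + i] = a * (1 - wj) + b * wj;
        }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bilinear_bwd(NumericVector dy, IntegerVector ydim,
                                        int H, int W) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  std::vector<int> ri0, ri1, cj0, cj1;
  std::vector<double> rw, cw;
  bilin_axis(H, Ho, ri0, ri1, rw);
  bilin_axis(W, Wo, cj0, cj1, cw);
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* g = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dst = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        double wj = cw[j];
        double* d0 = dst + (size_t)cj0[j] * H;
        double* d1 = dst + (size_t)cj1[j] * H;
        for (int i = 0; i < Ho; ++i) {
          double gv = g[(size_t)j * Ho + i];
          d0[ri0[i]] += gv * (1 - rw[i]) * (1 - wj);
          d0[ri1[i]] += gv * rw[i] * (1 - wj);
          d1[ri0[i]] += gv * (1 - rw[i]) * wj;
          d1[ri1[i]] += gv * rw[i] * wj;
        }
      }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// ---- 2x2 stride-2 transposed convolution ----

// [[Rcpp::export]]
NumericVector cpp_convT2_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int Co = wdim[3];
  NumericVector y((size_t)4 * H * W * Co * N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* dst = y.begin() + ((size_t)n * Co + co) * 4 * H * W;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* src = x.begin() + ((size_t)n * Ci + ci) * H * W;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double wv = w[a + 2 * b + 4 * (ci + (size_t)Ci * co)];
            for (int j = 0; j < W; ++j)
              for (int i = 0; i < H; ++i)
                dst[(size_t)(2 * j + b) * 2 * H + 2 * i + a] +=
                    wv * src[(size_t)j * H + i];
          }
      }
    }
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convT2_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim, NumericVector dy) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int Co = wdim[3];
  NumericVector dx((size_t)H * W * Ci * N);
  NumericVector dw((size_t)4 * Ci * Co);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* g = dy.begin() + ((size_t)n * Co + co) * 4 * H * W;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* src = x.begin() + ((size_t)n * Ci + ci) * H * W;
        double* dsrc = dx.begin() + ((size_t)n * Ci + ci) * H * W;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double wv = w[a + 2 * b + 4 * (ci + (size_t)Ci * co)];
            double acc = 0.0;
            for (int j = 0; j < W; ++j)
              for (int i = 0; i < H; ++i) {
                double gv = g[(size_t)(2 * j + b) * 2 * H + 2 * i + a];
                dsrc[(size_t)j * H + i] += wv * gv;
                acc += gv * src[(size_t)j * H + i];
              }
            dw[a + 2 * b + 4 * (ci + (size_t)Ci * co)] += acc;
          }
      }
    }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
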