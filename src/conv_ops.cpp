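// Convolution primitives for the autodiff engine.
//
// Tensor layout throughout: column-major R arrays of dim (H, W, C, N).
// Convolution weights: (kh, kw, C/groups, O).  All heavy lifting is
// im2col/col2im with the whole batch stacked into one BLAS GEMM per group.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill columns [col0, col0 + Ho*Wo) of K (kv x N*L) with patches of
// channels [c0, c0+Cg) of one sample.
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& K, size_t col0) {
  const size_t plane = (size_t)H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* kcol = K.colptr(col0 + ho + (size_t)Ho * wo);
      for (int cc = 0; cc < Cg; ++cc) {
        const double* xc = x + (size_t)(c0 + cc) * plane;
        for (int kj = 0; kj < kw; ++kj) {
          int w = wo * stride - pad + kj * dil;
          for (int ki = 0; ki < kh; ++ki) {
            int h = ho * stride - pad + ki * dil;
            kcol[ki + kh * (kj + kw * cc)] =
              (h >= 0 && h < H && w >= 0 && w < W)
                ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add columns [col0, col0 + Ho*Wo) of K onto channels [c0, c0+Cg).
static void col2im(double* x, int H, int W, int c0, int Cg,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, const arma::mat& K, size_t col0) {
  const size_t plane = (size_t)H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* kcol = K.colptr(col0 + ho + (size_t)Ho * wo);
      for (int cc = 0; cc < Cg; ++cc) {
        double* xc = x + (size_t)(c0 + cc) * plane;
        for (int kj = 0; kj < kw; ++kj) {
          int w = wo * stride - pad + kj * dil;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int h = ho * stride - pad + ki * dil;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += kcol[ki + kh * (kj + kw * cc)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector wdim,
                           NumericVector bias,
                           int stride, int pad, int dil, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], O = wdim[3];
  if (Cg * groups != C) stop("channel/group mismatch in conv forward");
  const int Ho = out_size(H, kh, stride, pad, dil);
  const int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  const int Og = O / groups;
  const size_t L = (size_t)Ho * Wo;
  const int kv = kh * kw * Cg;
  NumericVector y((size_t)L * O * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  arma::mat K(kv, L * N);
  const bool has_bias = bias.size() > 0;
  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n)
      im2col(x.begin() + (size_t)n * H * W * C, H, W, g * Cg, Cg,
             kh, kw, stride, pad, dil, Ho, Wo, K, (size_t)n * L);
    const arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)kv * g * Og,
                       kv, Og, false, true);
    arma::mat Y = K.t() * Wg;  // (N*L) x Og
    for (int n = 0; n < N; ++n) {
      double* yg = y.begin() + ((size_t)n * O + (size_t)g * Og) * L;
      for (int o = 0; o < Og; ++o) {
        const double* src = Y.colptr(o) + (size_t)n * L;
        double* dst = yg + (size_t)o * L;
        if (has_bias) {
          const double b = bias[g * Og + o];
          for (size_t l = 0; l < L; ++l) dst[l] = src[l] + b;
        } else {
          std::copy(src, src + L, dst);
        }
      }
    }
  }
  return y;
}

// Gather gy (Ho,Wo,O,N) group g into a stacked (N*L x Og) matrix.
static void gather_gy(const double* gy, int O, int Og, int g, int N,
                      size_t L, arma::mat& GY) {
  for (int n = 0; n < N; ++n) {
    const double* src0 = gy + ((size_t)n * O + (size_t)g * Og) * L;
    for (int o = 0; o < Og; ++o)
      std::copy(src0 + (size_t)o * L, src0 + (size_t)(o + 1) * L,
                GY.colptr(o) + (size_t)n * L);
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_gx(NumericVector gy, IntegerVector gydim,
                          NumericVector w, IntegerVector wdim,
                          IntegerVector xdim,
                          int stride, int pad, int dil, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], O = wdim[3];
  const int Ho = gydim[0], Wo = gydim[1];
  const int Og = O / groups;
  const size_t L = (size_t)Ho * Wo;
  const int kv = kh * kw * Cg;
  NumericVector gx((size_t)H * W * C * N);  // zero-initialised
  gx.attr("dim") = xdim;
  arma::mat GY(L * N, Og);
  for (int g = 0; g < groups; ++g) {
    gather_gy(gy.begin(), O, Og, g, N, L, GY);
    const arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)kv * g * Og,
                       kv, Og, false, true);
    arma::mat K = Wg * GY.t();  // kv x (N*L)
    for (int n = 0; n < N; ++n)
      col2im(gx.begin() + (size_t)n * H * W * C, H, W, g * Cg, Cg,
             kh, kw, stride, pad, dil, Ho, Wo, K, (size_t)n * L);
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv_gw(NumericVector x, IntegerVector xdim,
                          NumericVector gy, IntegerVector gydim,
                          IntegerVector wdim,
                          int stride, int pad, int dil, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], O = wdim[3];
  const int Ho = gydim[0], Wo = gydim[1];
  const int Og = O / groups;
  const size_t L = (size_t)Ho * Wo;
  const int kv = kh * kw * Cg;
  NumericVector gw((size_t)kv * O);
  gw.attr("dim") = wdim;
  arma::mat K(kv, L * N);
  arma::mat GY(L * N, Og);
  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n)
      im2col(x.begin() + (size_t)n * H * W * C, H, W, g * Cg, Cg,
             kh, kw, stride, pad, dil, Ho, Wo, K, (size_t)n * L);
    gather_gy(gy.begin(), O, Og, g, N, L, GY);
    arma::mat GWg(gw.begin() + (size_t)kv * g * Og, kv, Og, false, true);
    GWg += K * GY;
  }
  return gw;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  const size_t L = (size_t)Ho * Wo;
  NumericVector y(L * C * N);
  IntegerVector arg(L * C * N);  // 0-based flat index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * plane;
      const size_t base = ((size_t)n * C + c) * plane;
      double* yc = y.begin() + ((size_t)n * C + c) * L;
      int* ac = arg.begin() + ((size_t)n * C + c) * L;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; besti = base + h + (size_t)H * w; }
            }
          }
          yc[ho + (size_t)Ho * wo] = best;
          ac[ho + (size_t)Ho * wo] = (int)besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}
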