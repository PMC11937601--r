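// Convolution and pooling kernels.
//
// Array layout conventions (shared with the R side):
//   feature maps : dim c(H, W, C, N)      column-major, h fastest
//   dense kernels: dim c(kh, kw, Cin, Cout)
//   depthwise    : dim c(kh, kw, C)
// im2col rows are ordered r = dh + kh*(dw + kw*c), columns l = ho + Ho*wo,
// so a kernel array flattened over its first three axes is directly the
// (kh*kw*Cin) x Cout GEMM operand.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       arma::mat& cols) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int ws = wo * stride - pad + dw;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hs = ho * stride - pad + dh;
            double v = 0.0;
            if (hs >= 0 && hs < H && ws >= 0 && ws < W)
              v = x[hs + (R_xlen_t)H * (ws + (R_xlen_t)W * c)];
            cols(r, ho + Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int stride, int pad, double* dx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int ws = wo * stride - pad + dw;
          if (ws < 0 || ws >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hs = ho * stride - pad + dh;
            if (hs < 0 || hs >= H) continue;
            dx[hs + (R_xlen_t)H * (ws + (R_xlen_t)W * c)] += cols(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * C, L = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((R_xlen_t)L * Cout * N);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (R_xlen_t)H * W * C * n, H, W, C, kh, kw, stride, pad, cols);
    arma::mat o(out.begin() + (R_xlen_t)L * Cout * n, L, Cout, false, true);
    o = cols.t() * Wm;
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * C, L = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)K * Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (R_xlen_t)H * W * C * n, H, W, C, kh, kw, stride, pad, cols);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (R_xlen_t)L * Cout * n,
                  L, Cout, false, true);
    dWm += cols * dyn;
    arma::mat dcols = Wm * dyn.t();
    col2im_one(dcols, H, W, C, kh, kw, stride, pad,
               dx.begin() + (R_xlen_t)H * W * C * n);
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_forward(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cw = wd[2];
  if (Cw != C) stop("depthwise conv: one spatial filter per channel required");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)H * W * C * n;
    double* on = out.begin() + (R_xlen_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (R_xlen_t)H * W * c;
      const double* wc = w.begin() + (R_xlen_t)kh * kw * c;
      double* oc = on + (R_xlen_t)Ho * Wo * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int dw = 0; dw < kw; ++dw) {
            const int ws = wo * stride - pad + dw;
            if (ws < 0 || ws >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int hs = ho * stride - pad + dh;
              if (hs < 0 || hs >= H) continue;
              acc += wc[dh + kh * dw] * xc[hs + (R_xlen_t)H * ws];
            }
          }
          oc[ho + Ho * wo] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (R_xlen_t)H * W * C * n;
    const double* dyn = dy.begin() + (R_xlen_t)Ho * Wo * C * n;
    double* dxn = dx.begin() + (R_xlen_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (R_xlen_t)H * W * c;
      const double* dyc = dyn + (R_xlen_t)Ho * Wo * c;
      const double* wc = w.begin() + (R_xlen_t)kh * kw * c;
      double* dxc = dxn + (R_xlen_t)H * W * c;
      double* dwc = dw.begin() + (R_xlen_t)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyc[ho + Ho * wo];
          if (g == 0.0) continue;
          for (int dw2 = 0; dw2 < kw; ++dw2) {
            const int ws = wo * stride - pad + dw2;
            if (ws < 0 || ws >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int hs = ho * stride - pad + dh;
              if (hs < 0 || hs >= H) continue;
              dxc[hs + (R_xlen_t)H * ws] += g * wc[dh + kh * dw2];
              dwc[dh + kh * dw2] += g * xc[hs + (R_xlen_t)H * ws];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int dw = 0; dw < k; ++dw) {
            const int ws = wo * stride + dw;
            for (int dh = 0; dh < k; ++dh) {
              const int hs = ho * stride + dh;
              const double v = xc[hs + (R_xlen_t)H * ws];
              if (v > best) { best = v; bi = hs + (R_xlen_t)H * ws; }
            }
          }
          // out is (Ho,Wo,C,N) but we iterate c-major here; compute index
          const R_xlen_t oi = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          out[oi] = best;
          idx[oi] = (int)(base + bi);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
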