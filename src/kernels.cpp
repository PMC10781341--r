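// Dense numerical kernels for the network. Feature maps are R arrays with
// dim (H, W, C, N), column-major, so index = h + H*(w + W*(c + C*n)).
// Convolution weights have dim (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_size(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

static void im2col(const double* xp, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* plane = xp + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const double* src = plane + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            col(row, ho + (size_t)Ho * wo) = src[hi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, bool has_bias,
                             int stride, int pad, int dil) {
  IntegerVector xdim = x.attr("dim");
  IntegerVector wdim = w.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  int Ho = conv_out_size(H, kh, stride, pad, dil);
  int Wo = conv_out_size(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  int K = kh * kw * Cin;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  arma::mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    im2col(xp, H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat o = col.t() * Wm;  // (Ho*Wo) x Cout
    double* op = out.begin() + (size_t)n * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c) {
      double b = has_bias ? bias[c] : 0.0;
      const double* oc = o.colptr(c);
      double* dst = op + (size_t)c * Ho * Wo;
      for (int i = 0; i < Ho * Wo; ++i) dst[i] = oc[i] + b;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    bool has_bias, int stride, int pad, int dil,
                    bool need_gx) {
  IntegerVector xdim = x.attr("dim");
  IntegerVector wdim = w.attr("dim");
  IntegerVector gdim = gy.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  int Ho = gdim[0], Wo = gdim[1];
  int K = kh * kw * Cin;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = xdim;
  }
  NumericVector gw((size_t)kh * kw * Cin * Cout);
  gw.attr("dim") = wdim;
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  NumericVector gb(Cout);
  arma::mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    const double* gp = gy.begin() + (size_t)n * Ho * Wo * Cout;
    arma::mat gO(const_cast<double*>(gp), (size_t)Ho * Wo, Cout, false, true);
    im2col(xp, H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo, col);
    gWm += col * gO;  // K x Cout
    if (has_bias) {
      for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(gO.col(c));
    }
    if (need_gx) {
      arma::mat gcol = Wm * gO.t();  // K x (Ho*Wo), col2im scatter
      double* gxp = gx.begin() + (size_t)n * H * W * C;
      for (int c = 0; c < Cin; ++c) {
        double* plane = gxp + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            int row = ki + kh * (kj + kw * c);
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pad + kj * dil;
              if (wi < 0 || wi >= W) continue;
              double* dst = plane + (size_t)wi * H;
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - pad + ki * dil;
                if (hi < 0 || hi >= H) continue;
                dst[hi] += gcol(row, ho + (size_t)Ho * wo);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw, _["gb"] = gb);
}

// Per-channel mean and biased variance over (H, W, N).
// [[Rcpp::export]]
List cpp_bn2d_stats(NumericVector x) {
  IntegerVector xdim = x.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (plane * N);
    mean[c] = m;
    var[c] = s2 / (plane * N) - m * m;
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn2d_fwd(NumericVector x, NumericVector mean,
                           NumericVector invstd, NumericVector gamma,
                           NumericVector beta) {
  IntegerVector xdim = x.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = y.begin() + plane * (c + (size_t)C * n);
      double a = gamma[c] * invstd[c];
      double b = beta[c] - a * mean[c];
      for (size_t i = 0; i < plane; ++i) q[i] = a * p[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// Backward through batch norm. If train = true, mean/invstd were computed from
// this batch and their dependence on x is differentiated; otherwise they are
// constants (running statistics, evaluation mode).
// [[Rcpp::export]]
List cpp_bn2d_bwd(NumericVector x, NumericVector mean, NumericVector invstd,
                  NumericVector gamma, NumericVector gy, bool train) {
  IntegerVector xdim = x.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  double M = (double)plane * N;
  NumericVector gx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xhat = (p[i] - mean[c]) * invstd[c];
        sg += g[i];
        sgx += g[i] * xhat;
      }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      double* q = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        if (train) {
          double xhat = (p[i] - mean[c]) * invstd[c];
          q[i] = a * (g[i] - sg / M - xhat * sgx / M);
        } else {
          q[i] = a * g[i];
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xdim = x.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = conv_out_size(H, k, stride, pad, 1);
  int Wo = conv_out_size(W, k, stride, pad, 1);
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg(out.size());
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = out.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ap = arg.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = p[hi + (size_t)H * wi];
              if (v > best) { best = v; bidx = hi + H * wi; }
            }
          }
          q[ho + (size_t)Ho * wo] = best;
          ap[ho + (size_t)Ho * wo] = bidx;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax,
                              IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector gdim = gy.attr("dim");
  int Ho = gdim[0], Wo = gdim[1];
  NumericVector gx((size_t)H * W * C * N);
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* q = gx.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ap = argmax.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        if (ap[i] >= 0) q[ap[i]] += g[i];
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// Bilinear x2 upsampling with the half-pixel (align_corners = false) mapping:
// source coordinate s = (o + 0.5)/2 - 0.5, clamped to the image.
static void up2_coeffs(int out, int in, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(out); i1.resize(out); w1.resize(out);
  for (int o = 0; o < out; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int lo = (int)std::floor(s);
    int hi = lo + 1 < in ? lo + 1 : in - 1;
    i0[o] = lo; i1[o] = hi; w1[o] = s - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xdim = x.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_coeffs(Ho, H, h0, h1, hw);
  up2_coeffs(Wo, W, w0, w1v, ww);
  NumericVector out((size_t)Ho * Wo * C * N);
  size_t P = (size_t)C * N;
  for (size_t p = 0; p < P; ++p) {
    const double* src = x.begin() + (size_t)H * W * p;
    double* dst = out.begin() + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo) {
      int a = w0[wo], b = w1v[wo]; double fw = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        int c0 = h0[ho], c1 = h1[ho]; double fh = hw[ho];
        double v00 = src[c0 + (size_t)H * a], v10 = src[c1 + (size_t)H * a];
        double v01 = src[c0 + (size_t)H * b], v11 = src[c1 + (size_t)H * b];
        dst[ho + (size_t)Ho * wo] =
          (1 - fw) * ((1 - fh) * v00 + fh * v10) + fw * ((1 - fh) * v01 + fh * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_coeffs(Ho, H, h0, h1, hw);
  up2_coeffs(Wo, W, w0, w1v, ww);
  NumericVector gx((size_t)H * W * C * N);
  size_t P = (size_t)C * N;
  for (size_t p = 0; p < P; ++p) {
    double* dst = gx.begin() + (size_t)H * W * p;
    const double* g = gy.begin() + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo) {
      int a = w0[wo], b = w1v[wo]; double fw = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        int c0 = h0[ho], c1 = h1[ho]; double fh = hw[ho];
        double gv = g[ho + (size_t)Ho * wo];
        dst[c0 + (size_t)H * a] += (1 - fw) * (1 - fh) * gv;
        dst[c1 + (size_t)H * a] += (1 - fw) * fh * gv;
        dst[c0 + (size_t)H * b] += fw * (1 - fh) * gv;
        dst[c1 + (size_t)H * b] += fw * fh * gv;
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}
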