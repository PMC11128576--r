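// Dense tensor primitives for the package's small CNNs.
//
// Layout convention: image batches are R arrays with dim (H, W, C, N),
// column-major, doubles. Convolution weights are (k*k*Cin) x Cout matrices
// whose row index runs fastest over kernel row, then kernel column, then
// input channel — matching the im2col column order below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w + (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// rows of the im2col matrix: r = ho + Hout*(wo + Wout*n)
// cols: ki + k*(kj + k*ci)
// Valid output ranges per kernel offset are precomputed so the inner copy
// loops carry no bounds checks; out-of-range (padding) entries are zeroed
// segment-wise.
static inline void valid_range(int k_off, int stride, int pad, int in_size,
                               int out_size, int& lo, int& hi) {
  // in = out*stride - pad + k_off in [0, in_size)
  lo = 0;
  while (lo < out_size && lo * stride - pad + k_off < 0) ++lo;
  hi = out_size - 1;
  while (hi >= 0 && hi * stride - pad + k_off >= in_size) --hi;
}

static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int k, int stride, int pad, int Hout, int Wout) {
  arma::mat cols((arma::uword)Hout * Wout * N, (arma::uword)k * k * C);
  double* cp = cols.memptr();
  const arma::uword nrow = (arma::uword)Hout * Wout * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      int wlo, whi;
      valid_range(kj, stride, pad, W, Wout, wlo, whi);
      for (int ki = 0; ki < k; ++ki) {
        int hlo, hhi;
        valid_range(ki, stride, pad, H, Hout, hlo, hhi);
        arma::uword col = (arma::uword)ki + k * ((arma::uword)kj + k * (arma::uword)ci);
        double* base = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xn = x + (arma::uword)H * W * ((arma::uword)ci + (arma::uword)C * n);
          for (int wo = 0; wo < Wout; ++wo) {
            double* dst = base + (arma::uword)Hout * ((arma::uword)wo + (arma::uword)Wout * n);
            if (wo < wlo || wo > whi) {
              std::fill(dst, dst + Hout, 0.0);
              continue;
            }
            int wi = wo * stride - pad + kj;
            const double* src = xn + (std::ptrdiff_t)H * wi + (ki - pad);
            for (int ho = 0; ho < hlo; ++ho) dst[ho] = 0.0;
            if (stride == 1) {
              std::copy(src + hlo, src + hhi + 1, dst + hlo);
            } else {
              for (int ho = hlo; ho <= hhi; ++ho) dst[ho] = src[ho * stride];
            }
            for (int ho = hhi + 1; ho < Hout; ++ho) dst[ho] = 0.0;
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_acc(arma::mat& dcols, double* dx, int H, int W, int C, int N,
                       int k, int stride, int pad, int Hout, int Wout) {
  const double* cp = dcols.memptr();
  const arma::uword nrow = (arma::uword)Hout * Wout * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      int wlo, whi;
      valid_range(kj, stride, pad, W, Wout, wlo, whi);
      for (int ki = 0; ki < k; ++ki) {
        int hlo, hhi;
        valid_range(ki, stride, pad, H, Hout, hlo, hhi);
        arma::uword col = (arma::uword)ki + k * ((arma::uword)kj + k * (arma::uword)ci);
        const double* base = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* xn = dx + (arma::uword)H * W * ((arma::uword)ci + (arma::uword)C * n);
          for (int wo = wlo; wo <= whi; ++wo) {
            const double* src = base + (arma::uword)Hout * ((arma::uword)wo + (arma::uword)Wout * n);
            int wi = wo * stride - pad + kj;
            double* dst = xn + (std::ptrdiff_t)H * wi + (ki - pad);
            if (stride == 1) {
              for (int ho = hlo; ho <= hhi; ++ho) dst[ho] += src[ho];
            } else {
              for (int ho = hlo; ho <= hhi; ++ho) dst[ho * stride] += src[ho];
            }
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                             int stride, int pad) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int kk = w.nrow();
  int k = (int)std::lround(std::sqrt((double)(kk / C)));
  if (k * k * C != kk) stop("weight rows incompatible with input channels");
  int Cout = w.ncol();
  int Hout = (H + 2 * pad - k) / stride + 1;
  int Wout = (W + 2 * pad - k) / stride + 1;
  arma::mat cols = im2col(x.begin(), H, W, C, N, k, stride, pad, Hout, Wout);
  arma::mat wm(w.begin(), kk, Cout, false);
  arma::mat y = cols * wm; // (Hout*Wout*N) x Cout
  NumericVector out((R_xlen_t)Hout * Wout * Cout * N);
  double* op = out.begin();
  const double* yp = y.memptr();
  const arma::uword hw = (arma::uword)Hout * Wout;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double bc = b[co];
      const double* src = yp + (arma::uword)y.n_rows * co + hw * n;
      double* dst = op + hw * ((arma::uword)co + (arma::uword)Cout * n);
      for (arma::uword i = 0; i < hw; ++i) dst[i] = src[i] + bc;
    }
  out.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                    int stride, int pad) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dims4(dout);
  int Hout = dd[0], Wout = dd[1], Cout = dd[2];
  int kk = w.nrow();
  int k = (int)std::lround(std::sqrt((double)(kk / C)));
  // reshape dout to (Hout*Wout*N) x Cout
  arma::mat dy((arma::uword)Hout * Wout * N, Cout);
  const double* dp = dout.begin();
  double* dyp = dy.memptr();
  const arma::uword hw = (arma::uword)Hout * Wout;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dp + hw * ((arma::uword)co + (arma::uword)Cout * n);
      double* dst = dyp + (arma::uword)dy.n_rows * co + hw * n;
      std::copy(src, src + hw, dst);
    }
  arma::mat cols = im2col(x.begin(), H, W, C, N, k, stride, pad, Hout, Wout);
  arma::mat wm(w.begin(), kk, Cout, false);
  arma::mat dwm = cols.t() * dy;                  // (k*k*C) x Cout
  arma::rowvec dbm = arma::sum(dy, 0);            // 1 x Cout
  arma::mat dcols = dy * wm.t();                  // rows x (k*k*C)
  NumericVector dx((R_xlen_t)H * W * C * N);
  col2im_acc(dcols, dx.begin(), H, W, C, N, k, stride, pad, Hout, Wout);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix dw(kk, Cout);
  std::copy(dwm.begin(), dwm.end(), dw.begin());
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = dbm(co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool input dimensions must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = xp[idx4(2 * ho + di, 2 * wo + dj, c, n, H, W, C)];
              if (v > best) { best = v; bi = di + 2 * dj; }
            }
          arma::uword o = idx4(ho, wo, c, n, Ho, Wo, C);
          y[o] = best;
          arg[o] = bi;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector argmax, NumericVector dout) {
  IntegerVector d = dims4(dout);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho * 2, W = Wo * 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          arma::uword o = idx4(ho, wo, c, n, Ho, Wo, C);
          int bi = argmax[o];
          int di = bi % 2, dj = bi / 2;
          dx[idx4(2 * ho + di, 2 * wo + dj, c, n, H, W, C)] += dout[o];
        }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int f) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % f || W % f) stop("avgpool input dimensions must be divisible by the factor");
  int Ho = H / f, Wo = W / f;
  double inv = 1.0 / (f * f);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0;
          for (int dj = 0; dj < f; ++dj)
            for (int di = 0; di < f; ++di)
              s += xp[idx4(f * ho + di, f * wo + dj, c, n, H, W, C)];
          y[idx4(ho, wo, c, n, Ho, Wo, C)] = s * inv;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dout, int f) {
  IntegerVector d = dims4(dout);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho * f, W = Wo * f;
  double inv = 1.0 / (f * f);
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dout[idx4(ho, wo, c, n, Ho, Wo, C)] * inv;
          for (int dj = 0; dj < f; ++dj)
            for (int di = 0; di < f; ++di)
              dx[idx4(f * ho + di, f * wo + dj, c, n, H, W, C)] += g;
        }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, int f) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H * f, Wo = W * f;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          y[idx4(ho, wo, c, n, Ho, Wo, C)] = xp[idx4(ho / f, wo / f, c, n, H, W, C)];
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dout, int f) {
  IntegerVector d = dims4(dout);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho / f, W = Wo / f;
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dx[idx4(ho / f, wo / f, c, n, H, W, C)] += dout[idx4(ho, wo, c, n, Ho, Wo, C)];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// ---- batch norm helpers: per-channel moments over (H, W, N) ---------------

// [[Rcpp::export]]
List cpp_channel_moments(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::uword hw = (arma::uword)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * ((arma::uword)c + (arma::uword)C * n);
      for (arma::uword i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (hw * N);
    mu[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                         NumericVector mu, NumericVector inv_sd) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::uword hw = (arma::uword)H * W;
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    double a = gamma[c] * inv_sd[c];
    double b = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      arma::uword off = hw * ((arma::uword)c + (arma::uword)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      for (arma::uword i = 0; i < hw; ++i) q[i] = a * p[i] + b;
    }
  }
  y.attr("dim") = d;
  return y;
}

// backward through batch normalisation; train = 1 accounts for the
// dependence of the batch statistics on x, train = 0 treats them as frozen
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dout, NumericVector gamma,
                NumericVector mu, NumericVector inv_sd, int train) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::uword hw = (arma::uword)H * W;
  double m = (double)hw * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sd_ = 0, sdx = 0; // sum(dout), sum(dout * xhat)
    for (int n = 0; n < N; ++n) {
      arma::uword off = hw * ((arma::uword)c + (arma::uword)C * n);
      const double* px = x.begin() + off;
      const double* pd = dout.begin() + off;
      for (arma::uword i = 0; i < hw; ++i) {
        sd_ += pd[i];
        sdx += pd[i] * (px[i] - mu[c]) * inv_sd[c];
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd_;
    double a = gamma[c] * inv_sd[c];
    for (int n = 0; n < N; ++n) {
      arma::uword off = hw * ((arma::uword)c + (arma::uword)C * n);
      const double* px = x.begin() + off;
      const double* pd = dout.begin() + off;
      double* q = dx.begin() + off;
      if (train) {
        for (arma::uword i = 0; i < hw; ++i) {
          double xhat = (px[i] - mu[c]) * inv_sd[c];
          q[i] = a * (pd[i] - sd_ / m - xhat * sdx / m);
        }
      } else {
        for (arma::uword i = 0; i < hw; ++i) q[i] = a * pd[i];
      }
    }
  }
  dx.attr("dim") = d;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : slope * p[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector dout, double slope) {
  NumericVector dx(x.size());
  const double* p = x.begin();
  const double* pd = dout.begin();
  double* q = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? pd[i] : slope * pd[i];
  dx.attr("dim") = x.attr("dim");
  return dx;
}
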