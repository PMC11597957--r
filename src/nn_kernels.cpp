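// Convolution and pooling kernels for the in-package neural network layers.
// Array layout throughout: images/feature maps are (H, W, C, N) column-major
// (height fastest), convolution weights are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &d1, int &d2, int &d3,
                             int &d4) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

// Fill the im2col patch matrix P (kh*kw*C x oH*oW) for sample n.
// Row index r = ki + kh*(kj + kw*c) matches the column-major flattening of a
// (kh, kw, Cin) weight slice, so y = P' * Wm needs no reordering.
static void im2col_sample(const double *x, int H, int W, int C, int n, int kh,
                          int kw, int stride, int pad, int oH, int oW,
                          arma::mat &P) {
  const double *xn = x + (size_t)n * H * W * C;
  for (int c = 0; c < C; ++c) {
    const double *xc = xn + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        double *prow = P.memptr() + r; // stride between cols = P.n_rows
        for (int oj = 0; oj < oW; ++oj) {
          int w = oj * stride + kj - pad;
          for (int oi = 0; oi < oH; ++oi) {
            int h = oi * stride + ki - pad;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + (size_t)H * w];
            prow[(size_t)(oi + oH * oj) * P.n_rows] = v;
          }
        }
      }
    }
  }
}

// Scatter-add the columns of dP back into dx for sample n (col2im).
static void col2im_sample(const arma::mat &dP, double *dx, int H, int W, int C,
                          int n, int kh, int kw, int stride, int pad, int oH,
                          int oW) {
  double *xn = dx + (size_t)n * H * W * C;
  for (int c = 0; c < C; ++c) {
    double *xc = xn + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        const double *prow = dP.memptr() + r;
        for (int oj = 0; oj < oW; ++oj) {
          int w = oj * stride + kj - pad;
          if (w < 0 || w >= W) continue;
          for (int oi = 0; oi < oH; ++oi) {
            int h = oi * stride + ki - pad;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += prow[(size_t)(oi + oH * oj) * dP.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias, int stride, int pad) {
  int H, W, C, N, kh, kw, Cin, F;
  get_dims4(x, H, W, C, N);
  get_dims4(w, kh, kw, Cin, F);
  if (Cin != C) stop("channel mismatch between input and weights");
  int oH = (H + 2 * pad - kh) / stride + 1;
  int oW = (W + 2 * pad - kw) / stride + 1;
  if (oH < 1 || oW < 1) stop("kernel larger than padded input");

  NumericVector y((size_t)oH * oW * F * N);
  y.attr("dim") = IntegerVector::create(oH, oW, F, N);

  const arma::mat Wm(const_cast<double *>(w.begin()), (size_t)kh * kw * C, F,
                     false, true);
  arma::mat P((size_t)kh * kw * C, (size_t)oH * oW);
  arma::vec b;
  bool has_bias = bias.isNotNull();
  if (has_bias) b = as<arma::vec>(bias.get());

  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin(), H, W, C, n, kh, kw, stride, pad, oH, oW, P);
    arma::mat Yn(y.begin() + (size_t)n * oH * oW * F, (size_t)oH * oW, F,
                 false, true);
    Yn = P.t() * Wm;
    if (has_bias) Yn.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy, int stride,
                int pad, bool has_bias) {
  int H, W, C, N, kh, kw, Cin, F, oH, oW, F2, N2;
  get_dims4(x, H, W, C, N);
  get_dims4(w, kh, kw, Cin, F);
  get_dims4(dy, oH, oW, F2, N2);
  if (F2 != F || N2 != N) stop("gradient dims do not match");

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)kh * kw * C * F);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, F);

  const arma::mat Wm(const_cast<double *>(w.begin()), (size_t)kh * kw * C, F,
                     false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * C, F, false, true);
  arma::mat P((size_t)kh * kw * C, (size_t)oH * oW);
  arma::vec db(F, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin(), H, W, C, n, kh, kw, stride, pad, oH, oW, P);
    const arma::mat dYn(const_cast<double *>(dy.begin()) +
                            (size_t)n * oH * oW * F,
                        (size_t)oH * oW, F, false, true);
    dWm += P * dYn;
    arma::mat dP = Wm * dYn.t();
    col2im_sample(dP, dx.begin(), H, W, C, n, kh, kw, stride, pad, oH, oW);
    if (has_bias) db += arma::sum(dYn, 0).t();
  }

  List out = List::create(_["dx"] = dx, _["dw"] = dw);
  if (has_bias) out["db"] = NumericVector(db.begin(), db.end());
  return out;
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  if (oH < 1 || oW < 1) stop("pool window larger than padded input");

  NumericVector y((size_t)oH * oW * C * N);
  y.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector idx((size_t)oH * oW * C * N); // 1-based index into x
  idx.attr("dim") = IntegerVector::create(oH, oW, C, N);

  const double *xp = x.begin();
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (size_t)(c + (size_t)C * n) * H * W;
      size_t base = (size_t)(c + (size_t)C * n) * H * W;
      for (int oj = 0; oj < oW; ++oj) {
        for (int oi = 0; oi < oH; ++oi) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            int w = oj * stride + kj - pad;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = oi * stride + ki - pad;
              if (h < 0 || h >= H) continue;
              double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; besti = base + h + (size_t)H * w; }
            }
          }
          // column-major write order (oi fastest) matches p++ iteration below
          size_t o = (size_t)oi + oH * ((size_t)oj + oW * ((size_t)c + (size_t)C * n));
          y[o] = best;
          idx[o] = (int)(besti + 1);
          (void)p;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(IntegerVector idx, NumericVector dy,
                          IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// ---- split batch normalization ---------------------------------------------
// x: (H, W, C, N); per (channel, sample) slabs of length H*W are contiguous.

// [[Rcpp::export]]
List bn_train_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                  int numSplits, double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (N % numSplits != 0) stop("batch size not divisible by numSplits");
  int perSplit = N / numSplits;
  size_t HW = (size_t)H * W;
  double M = (double)HW * perSplit;

  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  NumericMatrix mus(C, numSplits), vars(C, numSplits), invstds(C, numSplits);

  for (int s = 0; s < numSplits; ++s) {
    for (int c = 0; c < C; ++c) {
      double sum = 0, sumsq = 0;
      for (int n = s * perSplit; n < (s + 1) * perSplit; ++n) {
        const double *p = x.begin() + HW * ((size_t)c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) { sum += p[i]; sumsq += p[i] * p[i]; }
      }
      double mu = sum / M;
      double var = sumsq / M - mu * mu;
      if (var < 0) var = 0;
      double invstd = 1.0 / std::sqrt(var + eps);
      mus(c, s) = mu; vars(c, s) = var; invstds(c, s) = invstd;
      double g = gamma[c];
      double b = beta[c];
      for (int n = s * perSplit; n < (s + 1) * perSplit; ++n) {
        const double *p = x.begin() + HW * ((size_t)c + (size_t)C * n);
        double *ph = xhat.begin() + HW * ((size_t)c + (size_t)C * n);
        double *po = out.begin() + HW * ((size_t)c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) {
          double xh = (p[i] - mu) * invstd;
          ph[i] = xh;
          po[i] = g * xh + b;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mus"] = mus,
                      _["vars"] = vars, _["invstds"] = invstds);
}

// [[Rcpp::export]]
List bn_train_bwd(NumericVector xhat, NumericVector gamma,
                  NumericMatrix invstds, NumericVector dy, int numSplits) {
  int H, W, C, N;
  get_dims4(xhat, H, W, C, N);
  int perSplit = N / numSplits;
  size_t HW = (size_t)H * W;
  double M = (double)HW * perSplit;

  NumericVector dx(xhat.size());
  dx.attr("dim") = xhat.attr("dim");
  NumericVector dgamma(C), dbeta(C);

  for (int s = 0; s < numSplits; ++s) {
    for (int c = 0; c < C; ++c) {
      double sum_dy = 0, sum_dyxh = 0;
      for (int n = s * perSplit; n < (s + 1) * perSplit; ++n) {
        const double *ph = xhat.begin() + HW * ((size_t)c + (size_t)C * n);
        const double *pd = dy.begin() + HW * ((size_t)c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) {
          sum_dy += pd[i];
          sum_dyxh += pd[i] * ph[i];
        }
      }
      dgamma[c] += sum_dyxh;
      dbeta[c] += sum_dy;
      // dxhat = dy * gamma; dx = invstd/M * (M*dxhat - sum(dxhat)
      //         - xhat * sum(dxhat*xhat))
      double g = gamma[c];
      double t1 = g * sum_dy / M;
      double t2 = g * sum_dyxh / M;
      double isd = invstds(c, s);
      for (int n = s * perSplit; n < (s + 1) * perSplit; ++n) {
        const double *ph = xhat.begin() + HW * ((size_t)c + (size_t)C * n);
        const double *pd = dy.begin() + HW * ((size_t)c + (size_t)C * n);
        double *px = dx.begin() + HW * ((size_t)c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i)
          px[i] = isd * (g * pd[i] - t1 - ph[i] * t2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector bn_eval_fwd(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector runningMean,
                          NumericVector runningVar, double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  size_t HW = (size_t)H * W;
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = gamma[c] / std::sqrt(runningVar[c] + eps);
      double b = beta[c] - runningMean[c] * a;
      const double *p = x.begin() + HW * ((size_t)c + (size_t)C * n);
      double *po = out.begin() + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) po[i] = a * p[i] + b;
    }
  }
  return out;
}
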