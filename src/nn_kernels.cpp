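// Minimal conv-net kernels: standard and depthwise 2D convolution and 2x2
// max-pooling, forward and backward, on batches stored as R arrays with
// dim (h, w, c, n) in column-major order. Convolutions use im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &h, int &w, int &c,
                             int &n) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array");
  h = d[0]; w = d[1]; c = d[2]; n = d[3];
}

// fill cols (npos x kh*kw*cin) from one sample block (h*w*cin doubles)
static void im2col(const double *xs, int h, int w, int cin, int kh, int kw,
                   int stride, int pad, int ho, int wo, arma::mat &cols) {
  cols.zeros();
  const int npos = ho * wo;
  for (int c = 0; c < cin; ++c) {
    const double *xc = xs + (size_t)c * h * w;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        double *col = cols.colptr(q);
        for (int oj = 0; oj < wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= w) continue;
          for (int oi = 0; oi < ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= h) continue;
            col[oi + ho * oj] = xc[ii + h * jj];
          }
        }
      }
    }
  }
  (void)npos;
}

// scatter-add dcols back into one dx sample block
static void col2im(const arma::mat &dcols, int h, int w, int cin, int kh,
                   int kw, int stride, int pad, int ho, int wo, double *dxs) {
  for (int c = 0; c < cin; ++c) {
    double *dxc = dxs + (size_t)c * h * w;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        const double *col = dcols.colptr(q);
        for (int oj = 0; oj < wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= w) continue;
          for (int oi = 0; oi < ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= h) continue;
            dxc[ii + h * jj] += col[oi + ho * oj];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector W,
                             Nullable<NumericVector> bias, int stride,
                             int pad) {
  int h, w, cin, n;
  get_dims4(x, h, w, cin, n);
  IntegerVector wd = W.attr("dim");
  if (wd.size() != 4 || wd[2] != cin) stop("weight/input channel mismatch");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  const int ho = (h + 2 * pad - kh) / stride + 1;
  const int wo = (w + 2 * pad - kw) / stride + 1;
  const int npos = ho * wo;

  NumericVector y((size_t)npos * cout * n);
  y.attr("dim") = IntegerVector::create(ho, wo, cout, n);

  arma::mat Wm(const_cast<double *>(W.begin()), (size_t)kh * kw * cin, cout,
               false, true);
  arma::mat cols(npos, (size_t)kh * kw * cin);
  arma::rowvec b;
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    b = arma::rowvec(bb.begin(), cout);
  }
  for (int s = 0; s < n; ++s) {
    const double *xs = x.begin() + (size_t)s * h * w * cin;
    im2col(xs, h, w, cin, kh, kw, stride, pad, ho, wo, cols);
    arma::mat ys(y.begin() + (size_t)s * npos * cout, npos, cout, false,
                 true);
    ys = cols * Wm;
    if (bias.isNotNull()) ys.each_row() += b;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector W, NumericVector dy,
                    int stride, int pad, bool has_bias) {
  int h, w, cin, n;
  get_dims4(x, h, w, cin, n);
  IntegerVector wd = W.attr("dim");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  const int ho = (h + 2 * pad - kh) / stride + 1;
  const int wo = (w + 2 * pad - kw) / stride + 1;
  const int npos = ho * wo;

  NumericVector dx((size_t)h * w * cin * n);
  dx.attr("dim") = IntegerVector::create(h, w, cin, n);
  NumericVector dW((size_t)kh * kw * cin * cout);
  dW.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  NumericVector db(cout);

  arma::mat Wm(const_cast<double *>(W.begin()), (size_t)kh * kw * cin, cout,
               false, true);
  arma::mat dWm(dW.begin(), (size_t)kh * kw * cin, cout, false, true);
  arma::mat cols(npos, (size_t)kh * kw * cin);

  for (int s = 0; s < n; ++s) {
    const double *xs = x.begin() + (size_t)s * h * w * cin;
    im2col(xs, h, w, cin, kh, kw, stride, pad, ho, wo, cols);
    arma::mat dys(const_cast<double *>(dy.begin()) + (size_t)s * npos * cout,
                  npos, cout, false, true);
    dWm += cols.t() * dys;
    arma::mat dcols = dys * Wm.t();
    col2im(dcols, h, w, cin, kh, kw, stride, pad, ho, wo,
           dx.begin() + (size_t)s * h * w * cin);
    if (has_bias) {
      arma::rowvec colsum = arma::sum(dys, 0);
      for (int o = 0; o < cout; ++o) db[o] += colsum[o];
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// depthwise conv, stride 1, 'same' padding; W dim (kh, kw, c).
// Implemented as kh*kw shifted submatrix accumulations per channel.

// overlap of the kernel tap (ki, kj) between input and output planes
static inline bool tap_ranges(int h, int w, int ki, int kj, int ph, int pw,
                              int &i0, int &i1, int &j0, int &j1) {
  const int di = ki - ph, dj = kj - pw;   // input offset relative to output
  i0 = std::max(0, -di); i1 = std::min(h, h - di) - 1;
  j0 = std::max(0, -dj); j1 = std::min(w, w - dj) - 1;
  return i0 <= i1 && j0 <= j1;
}

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector W) {
  int h, w, c, n;
  get_dims4(x, h, w, c, n);
  IntegerVector wd = W.attr("dim");
  if (wd.size() != 3 || wd[2] != c) stop("depthwise weight mismatch");
  const int kh = wd[0], kw = wd[1];
  const int ph = kh / 2, pw = kw / 2;

  NumericVector y((size_t)h * w * c * n);
  y.attr("dim") = IntegerVector::create(h, w, c, n);
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const arma::mat xc(const_cast<double *>(x.begin()) +
                         (size_t)(s * c + ch) * h * w, h, w, false, true);
      arma::mat yc(y.begin() + (size_t)(s * c + ch) * h * w, h, w, false,
                   true);
      const double *wc = W.begin() + (size_t)ch * kh * kw;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          if (wv == 0.0) continue;
          int i0, i1, j0, j1;
          if (!tap_ranges(h, w, ki, kj, ph, pw, i0, i1, j0, j1)) continue;
          const int di = ki - ph, dj = kj - pw;
          yc.submat(i0, j0, i1, j1) +=
            wv * xc.submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector W, NumericVector dy) {
  int h, w, c, n;
  get_dims4(x, h, w, c, n);
  IntegerVector wd = W.attr("dim");
  const int kh = wd[0], kw = wd[1];
  const int ph = kh / 2, pw = kw / 2;

  NumericVector dx((size_t)h * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  NumericVector dW((size_t)kh * kw * c);
  dW.attr("dim") = IntegerVector::create(kh, kw, c);

  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const arma::mat xc(const_cast<double *>(x.begin()) +
                         (size_t)(s * c + ch) * h * w, h, w, false, true);
      const arma::mat dyc(const_cast<double *>(dy.begin()) +
                          (size_t)(s * c + ch) * h * w, h, w, false, true);
      arma::mat dxc(dx.begin() + (size_t)(s * c + ch) * h * w, h, w, false,
                    true);
      const double *wc = W.begin() + (size_t)ch * kh * kw;
      double *dwc = dW.begin() + (size_t)ch * kh * kw;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          int i0, i1, j0, j1;
          if (!tap_ranges(h, w, ki, kj, ph, pw, i0, i1, j0, j1)) continue;
          const int di = ki - ph, dj = kj - pw;
          dwc[ki + kh * kj] += arma::accu(
            dyc.submat(i0, j0, i1, j1) %
            xc.submat(i0 + di, j0 + dj, i1 + di, j1 + dj));
          dxc.submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
            wc[ki + kh * kj] * dyc.submat(i0, j0, i1, j1);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// ---- batch-norm helpers: one pass per-channel stats and affine maps ----

// per-channel mean and (biased) variance over batch and space
// [[Rcpp::export]]
List bn_moments_cpp(NumericVector x) {
  int h, w, c, n;
  get_dims4(x, h, w, c, n);
  const size_t hw = (size_t)h * w;
  NumericVector mean(c), var(c);
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const double *xc = x.begin() + (hw * (s * c + ch));
      double s1 = 0, s2 = 0;
      for (size_t k = 0; k < hw; ++k) { s1 += xc[k]; s2 += xc[k] * xc[k]; }
      mean[ch] += s1; var[ch] += s2;
    }
  }
  const double m = (double)hw * n;
  for (int ch = 0; ch < c; ++ch) {
    mean[ch] /= m;
    var[ch] = std::max(var[ch] / m - mean[ch] * mean[ch], 0.0);
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// xhat = (x - mean) * inv;  y = gamma * xhat + beta  (per channel)
// [[Rcpp::export]]
List bn_norm_cpp(NumericVector x, NumericVector mean, NumericVector inv,
                 NumericVector gamma, NumericVector beta) {
  int h, w, c, n;
  get_dims4(x, h, w, c, n);
  const size_t hw = (size_t)h * w;
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = x.attr("dim");
  y.attr("dim") = x.attr("dim");
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const double *xc = x.begin() + hw * (s * c + ch);
      double *hc = xhat.begin() + hw * (s * c + ch);
      double *yc = y.begin() + hw * (s * c + ch);
      const double mu = mean[ch], iv = inv[ch], g = gamma[ch], b = beta[ch];
      for (size_t k = 0; k < hw; ++k) {
        const double xh = (xc[k] - mu) * iv;
        hc[k] = xh;
        yc[k] = g * xh + b;
      }
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// full batch-norm backward given dy, xhat, gamma, inv
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector inv) {
  int h, w, c, n;
  get_dims4(dy, h, w, c, n);
  const size_t hw = (size_t)h * w;
  NumericVector dgamma(c), dbeta(c);
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const double *dc = dy.begin() + hw * (s * c + ch);
      const double *hc = xhat.begin() + hw * (s * c + ch);
      double s1 = 0, s2 = 0;
      for (size_t k = 0; k < hw; ++k) { s1 += dc[k]; s2 += dc[k] * hc[k]; }
      dbeta[ch] += s1; dgamma[ch] += s2;
    }
  }
  const double m = (double)hw * n;
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const double *dc = dy.begin() + hw * (s * c + ch);
      const double *hc = xhat.begin() + hw * (s * c + ch);
      double *xc = dx.begin() + hw * (s * c + ch);
      const double a = gamma[ch] * inv[ch];
      const double b = dbeta[ch] / m, g2 = dgamma[ch] / m;
      for (size_t k = 0; k < hw; ++k) {
        xc[k] = a * (dc[k] - b - hc[k] * g2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2 max-pool, stride 2; h and w must be even
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int h, w, c, n;
  get_dims4(x, h, w, c, n);
  if (h % 2 || w % 2) stop("max-pooling requires even spatial dimensions");
  const int ho = h / 2, wo = w / 2;
  NumericVector y((size_t)ho * wo * c * n);
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  IntegerVector idx((size_t)ho * wo * c * n);  // 0-based index into x

  size_t p = 0;
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const size_t base = (size_t)(s * c + ch) * h * w;
      for (int oj = 0; oj < wo; ++oj) {
        for (int oi = 0; oi < ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const size_t q = base + (2 * oi + di) + (size_t)h *
                               (2 * oj + dj);
              if (x[q] > best) { best = x[q]; bidx = q; }
            }
          }
          // output memory order matches loop order: oi fastest, then oj,
          // then ch, then s
          const size_t po = (size_t)(s * c + ch) * ho * wo + oi +
                            (size_t)ho * oj;
          y[po] = best;
          idx[po] = (int)bidx;
          ++p;
        }
      }
    }
  }
  (void)p;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[idx[k]] += dy[k];
  return dx;
}
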