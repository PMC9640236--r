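// Numerical kernels for the network layers. All activation tensors are R
// double arrays with dim (H, W, C, N), column-major. Convolutions run as
// im2col + single-precision GEMM (the accumulation order is fixed, so
// results are bit-reproducible run to run); everything else is double.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// im2col: rows ordered (h, w, n), columns ordered (dx fastest, dy, c) to
// match the weight matrix layout (k*k*Cin rows, Cout cols).
static void im2col(const double* x, int H, int W, int C, int N,
                   int k, int pad, arma::fmat& col) {
  const int HW = H * W;
  const long HWN = (long)HW * N;
  for (int c = 0; c < C; ++c) {
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int q = dx + k * (dy + k * c);
        float* dst = col.colptr(q);
        const int h0 = std::max(0, pad - dy);
        const int h1 = std::min(H, H + pad - dy);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + (long)HW * (c + (long)C * n);
          for (int w = 0; w < W; ++w) {
            const int wi = w + dx - pad;
            float* d = dst + (long)HW * n + (long)H * w;
            if (wi < 0 || wi >= W) {
              std::fill(d, d + H, 0.0f);
            } else {
              const double* s = xs + (long)H * wi + (dy - pad);
              for (int h = 0; h < h0; ++h) d[h] = 0.0f;
              for (int h = h0; h < h1; ++h) d[h] = (float)s[h];
              for (int h = h1; h < H; ++h) d[h] = 0.0f;
            }
          }
        }
      }
    }
  }
  (void)HWN;
}

// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, NumericMatrix Wm,
                    NumericVector b, int k, int pad,
                    bool keep_col = false) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Cout = Wm.ncol();
  const int K2C = Wm.nrow();
  const long HWN = (long)H * W * N;
  arma::fmat* colp = new arma::fmat(HWN, K2C);
  im2col(REAL(x), H, W, C, N, k, pad, *colp);
  arma::fmat Wf(K2C, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < K2C; ++i) Wf(i, j) = (float)Wm(i, j);
  arma::fmat Y = (*colp) * Wf;
  NumericVector y = alloc4(H, W, Cout, N);
  double* yp = REAL(y);
  const int HW = H * W;
  for (int co = 0; co < Cout; ++co) {
    const float* src = Y.colptr(co);
    const double bb = b[co];
    for (int n = 0; n < N; ++n) {
      double* d = yp + (long)HW * (co + (long)Cout * n);
      const float* s = src + (long)HW * n;
      for (int i = 0; i < HW; ++i) d[i] = (double)s[i] + bb;
    }
  }
  if (keep_col) {
    XPtr<arma::fmat> px(colp, true);
    return List::create(_["y"] = y, _["col"] = px);
  }
  delete colp;
  return List::create(_["y"] = y, _["col"] = R_NilValue);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy,
                    int k, int pad, SEXP col_cache = R_NilValue,
                    bool need_dx = true) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Cout = Wm.ncol();
  const int K2C = Wm.nrow();
  const int HW = H * W;
  const long HWN = (long)HW * N;

  arma::fmat local_col;
  arma::fmat* colp;
  if (col_cache != R_NilValue) {
    XPtr<arma::fmat> px(col_cache);
    colp = px.get();
  } else {
    local_col.set_size(HWN, K2C);
    im2col(REAL(x), H, W, C, N, k, pad, local_col);
    colp = &local_col;
  }
  const arma::fmat& col = *colp;

  arma::fmat dY(HWN, Cout);
  const double* dyp = REAL(dy);
  for (int co = 0; co < Cout; ++co) {
    float* d = dY.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* s = dyp + (long)HW * (co + (long)Cout * n);
      for (int i = 0; i < HW; ++i) d[(long)HW * n + i] = (float)s[i];
    }
  }

  arma::fmat dWf = col.t() * dY;             // K2C x Cout
  NumericMatrix dW(K2C, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < K2C; ++i) dW(i, j) = (double)dWf(i, j);

  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    const float* d = dY.colptr(co);
    for (long i = 0; i < HWN; ++i) s += (double)d[i];
    db[co] = s;
  }

  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dW"] = dW, _["db"] = db);

  arma::fmat Wf(K2C, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < K2C; ++i) Wf(i, j) = (float)Wm(i, j);
  arma::fmat dcol = dY * Wf.t();             // HWN x K2C

  NumericVector dxv = alloc4(H, W, C, N);
  double* dxp = REAL(dxv);
  for (int c = 0; c < C; ++c) {
    for (int dyk = 0; dyk < k; ++dyk) {
      for (int dxk = 0; dxk < k; ++dxk) {
        const int q = dxk + k * (dyk + k * c);
        const float* src = dcol.colptr(q);
        const int h0 = std::max(0, pad - dyk);
        const int h1 = std::min(H, H + pad - dyk);
        for (int n = 0; n < N; ++n) {
          double* xs = dxp + (long)HW * (c + (long)C * n);
          for (int w = 0; w < W; ++w) {
            const int wi = w + dxk - pad;
            if (wi < 0 || wi >= W) continue;
            const float* s = src + (long)HW * n + (long)H * w;
            double* d = xs + (long)H * wi + (dyk - pad);
            for (int h = h0; h < h1; ++h) d[h] += (double)s[h];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int HW = H * W;
  const long M = (long)HW * N;
  NumericVector mean(C), var(C), invstd(C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double mu = s / M;
    double v = s2 / M - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v; invstd[c] = 1.0 / std::sqrt(v + eps);
  }
  NumericVector y = alloc4(H, W, C, N);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c] * invstd[c], bb = beta[c], mu = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + (long)HW * (c + (long)C * n);
      double* q = yp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) q[i] = g * (p[i] - mu) + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector dy,
                NumericVector mean, NumericVector invstd) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int HW = H * W;
  const long M = (long)HW * N;
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  NumericVector dgamma(C), dbeta(C);
  NumericVector dxv = alloc4(H, W, C, N);
  double* dxp = REAL(dxv);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sd = 0.0, sdx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = xp + (long)HW * (c + (long)C * n);
      const double* pd = dp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) {
        sd += pd[i];
        sdx += pd[i] * (px[i] - mu) * is;
      }
    }
    dbeta[c] = sd; dgamma[c] = sdx;
    const double g = gamma[c];
    const double m1 = sd / M, m2 = sdx / M;
    for (int n = 0; n < N; ++n) {
      const double* px = xp + (long)HW * (c + (long)C * n);
      const double* pd = dp + (long)HW * (c + (long)C * n);
      double* pq = dxp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) {
        const double xh = (px[i] - mu) * is;
        pq[i] = g * is * (pd[i] - m1 - xh * m2);
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_bn_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector rmean,
                          NumericVector rvar, double eps) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int HW = H * W;
  NumericVector y = alloc4(H, W, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c] * is, bb = beta[c], mu = rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + (long)HW * (c + (long)C * n);
      double* q = yp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) q[i] = g * (p[i] - mu) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx((long)Ho * Wo * C * N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  long o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long base = (long)H * W * (c + (long)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          long best = base + (long)H * (2 * w) + 2 * h;
          double bv = xp[best];
          const long cands[3] = {base + (long)H * (2 * w) + 2 * h + 1,
                                 base + (long)H * (2 * w + 1) + 2 * h,
                                 base + (long)H * (2 * w + 1) + 2 * h + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cands[t]] > bv) { bv = xp[cands[t]]; best = cands[t]; }
          // column-major output offset for (h, w, c, n)
          yp[(long)Ho * Wo * (c + (long)C * n) + (long)Ho * w + h] = bv;
          ip[(long)Ho * Wo * (c + (long)C * n) + (long)Ho * w + h] = (int)best;
          ++o;
        }
    }
  (void)o;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector dims_x) {
  NumericVector dxv = alloc4(dims_x[0], dims_x[1], dims_x[2], dims_x[3]);
  double* dxp = REAL(dxv);
  const double* dp = REAL(dy);
  const int* ip = INTEGER(idx);
  const long n = idx.size();
  for (long i = 0; i < n; ++i) dxp[ip[i]] += dp[i];
  return dxv;
}

// Bilinear 2x upsampling, half-pixel centers (align_corners = FALSE):
// output i samples input coordinate i/2 - 0.25, clamped at the border.
static void up2_axis(int Ho, int H, std::vector<int>& i0,
                     std::vector<int>& i1, std::vector<double>& t) {
  i0.resize(Ho); i1.resize(Ho); t.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    const double src = 0.5 * i - 0.25;
    const int f = (int)std::floor(src);
    double tt = src - f;
    int a = clampi(f, 0, H - 1), b = clampi(f + 1, 0, H - 1);
    i0[i] = a; i1[i] = b; t[i] = tt;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> th, tw;
  up2_axis(Ho, H, h0, h1, th);
  up2_axis(Wo, W, w0, w1, tw);
  NumericVector y = alloc4(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* s = xp + (long)H * W * (c + (long)C * n);
      double* d = yp + (long)Ho * Wo * (c + (long)C * n);
      for (int w = 0; w < Wo; ++w) {
        const double* s0 = s + (long)H * w0[w];
        const double* s1 = s + (long)H * w1[w];
        const double a = 1.0 - tw[w], bwt = tw[w];
        double* dc = d + (long)Ho * w;
        for (int h = 0; h < Ho; ++h) {
          const double top = a * s0[h0[h]] + bwt * s1[h0[h]];
          const double bot = a * s0[h1[h]] + bwt * s1[h1[h]];
          dc[h] = (1.0 - th[h]) * top + th[h] * bot;
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector dims_x) {
  const int H = dims_x[0], W = dims_x[1], C = dims_x[2], N = dims_x[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> th, tw;
  up2_axis(Ho, H, h0, h1, th);
  up2_axis(Wo, W, w0, w1, tw);
  NumericVector dxv = alloc4(H, W, C, N);
  double* dxp = REAL(dxv);
  const double* dp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* d = dxp + (long)H * W * (c + (long)C * n);
      const double* s = dp + (long)Ho * Wo * (c + (long)C * n);
      for (int w = 0; w < Wo; ++w) {
        const double a = 1.0 - tw[w], bwt = tw[w];
        const int wa = w0[w], wb = w1[w];
        const double* sc = s + (long)Ho * w;
        for (int h = 0; h < Ho; ++h) {
          const double g = sc[h];
          const double gt = (1.0 - th[h]) * g, gb = th[h] * g;
          d[(long)H * wa + h0[h]] += a * gt;
          d[(long)H * wb + h0[h]] += bwt * gt;
          d[(long)H * wa + h1[h]] += a * gb;
          d[(long)H * wb + h1[h]] += bwt * gb;
        }
      }
    }
  return dxv;
}

// Elementwise product with a single-channel map, broadcast over channels.
// [[Rcpp::export]]
NumericVector cpp_mulb_fwd(NumericVector x, NumericVector a) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int HW = H * W;
  NumericVector y = alloc4(H, W, C, N);
  const double* xp = REAL(x);
  const double* ap = REAL(a);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    const double* an = ap + (long)HW * n;
    for (int c = 0; c < C; ++c) {
      const double* p = xp + (long)HW * (c + (long)C * n);
      double* q = yp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) q[i] = p[i] * an[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_mulb_bwd(NumericVector x, NumericVector a, NumericVector dy) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int HW = H * W;
  NumericVector dxv = alloc4(H, W, C, N);
  NumericVector dav = alloc4(H, W, 1, N);
  const double* xp = REAL(x);
  const double* ap = REAL(a);
  const double* dp = REAL(dy);
  double* dxp = REAL(dxv);
  double* dap = REAL(dav);
  for (int n = 0; n < N; ++n) {
    const double* an = ap + (long)HW * n;
    double* dan = dap + (long)HW * n;
    for (int c = 0; c < C; ++c) {
      const double* px = xp + (long)HW * (c + (long)C * n);
      const double* pd = dp + (long)HW * (c + (long)C * n);
      double* pq = dxp + (long)HW * (c + (long)C * n);
      for (int i = 0; i < HW; ++i) {
        pq[i] = pd[i] * an[i];
        dan[i] += pd[i] * px[i];
      }
    }
  }
  return List::create(_["dx"] = dxv, _["da"] = dav);
}

// [[Rcpp::export]]
NumericVector cpp_concat_c(List xs) {
  const int m = xs.size();
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> Cs(m);
  for (int t = 0; t < m; ++t) {
    NumericVector xi = xs[t];
    IntegerVector d = xi.attr("dim");
    if (t == 0) { H = d[0]; W = d[1]; N = d[3]; }
    Cs[t] = d[2]; Ctot += d[2];
  }
  NumericVector y = alloc4(H, W, Ctot, N);
  double* yp = REAL(y);
  const long HW = (long)H * W;
  int coff = 0;
  for (int t = 0; t < m; ++t) {
    NumericVector xi = xs[t];
    const double* p = REAL(xi);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cs[t]; ++c) {
        const double* s = p + HW * (c + (long)Cs[t] * n);
        double* d = yp + HW * ((coff + c) + (long)Ctot * n);
        std::copy(s, s + HW, d);
      }
    coff += Cs[t];
  }
  return y;
}

// Inverse-mapped affine warp of a single 2D image (rows x cols matrix).
// m = c(a11,a21,a12,a22,t1,t2): input = A %*% output + t, coords centered.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector m,
                              bool bilinear) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double cy = 0.5 * (H - 1), cx = 0.5 * (W - 1);
  for (int j = 0; j < W; ++j) {
    const double xo = j - cx;
    for (int i = 0; i < H; ++i) {
      const double yo = i - cy;
      const double yi = m[0] * yo + m[2] * xo + m[4] + cy;
      const double xi = m[1] * yo + m[3] * xo + m[5] + cx;
      if (bilinear) {
        const int y0 = (int)std::floor(yi), x0 = (int)std::floor(xi);
        const double ty = yi - y0, tx = xi - x0;
        double acc = 0.0;
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const int yy = y0 + dy, xx = x0 + dx;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            const double wgt = (dy ? ty : 1 - ty) * (dx ? tx : 1 - tx);
            acc += wgt * img(yy, xx);
          }
        out(i, j) = acc;
      } else {
        const int yy = (int)std::lround(yi), xx = (int)std::lround(xi);
        out(i, j) = (yy < 0 || yy >= H || xx < 0 || xx >= W)
                        ? 0.0 : img(yy, xx);
      }
    }
  }
  return out;
}

// In-place Adam update: p -= lr * (m/c1) / (sqrt(v/c2) + 1e-8), with the
// moment buffers updated in place as well. Gradients arrive pre-adjusted
// for weight decay.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector m, NumericVector v,
                     NumericVector g, double lr, double b1, double b2,
                     double c1, double c2) {
  const R_xlen_t n = p.size();
  double* pp = REAL(p); double* pm = REAL(m);
  double* pv = REAL(v); const double* pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + 1e-8);
  }
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); double* yp = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector g) {
  NumericVector d(x.size());
  d.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); const double* gp = REAL(g);
  double* dp = REAL(d);
  for (R_xlen_t i = 0; i < x.size(); ++i) dp[i] = xp[i] > 0 ? gp[i] : 0.0;
  return d;
}
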