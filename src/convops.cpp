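// Convolution primitives for the autograd engine.
//
// Array layout convention: image stacks are R arrays [H, W, C, N]
// (column-major), so each channel plane is a contiguous H x W matrix.
// Patches are materialized row-major-by-pixel ("im2row", [P, K] with
// P = Ho*Wo output pixels and K = kh*kw*C taps) so that stride-1 kernels
// copy long contiguous column segments instead of kh-length snippets.
// K columns are packed (ki, kj, c) fastest-to-slowest, matching the
// column-major flatten of a weight array [kh, kw, Cin, Cout].

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather patches of one image into R [P, K]
static void im2row_one(const double* x, int H, int W, int C,
                       int kh, int kw, int st, int pad,
                       arma::mat& R) {
  const int Ho = (H + 2 * pad - kh) / st + 1;
  const int Wo = (W + 2 * pad - kw) / st + 1;
  const size_t P = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* col = R.colptr(ki + kh * (kj + kw * c));
        if (st == 1) {
          // hi = ho + ki - pad, wi = wo + kj - pad
          const int lead = std::max(0, pad - ki);
          const int tail = std::min(Ho, H - ki + pad);
          for (int wo = 0; wo < Wo; ++wo) {
            double* dst = col + (size_t)wo * Ho;
            const int wi = wo + kj - pad;
            if (wi < 0 || wi >= W || tail <= lead) {
              std::memset(dst, 0, sizeof(double) * Ho);
              continue;
            }
            if (lead > 0) std::memset(dst, 0, sizeof(double) * lead);
            std::memcpy(dst + lead, plane + (size_t)wi * H + (lead + ki - pad),
                        sizeof(double) * (tail - lead));
            if (tail < Ho) std::memset(dst + tail, 0, sizeof(double) * (Ho - tail));
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            double* dst = col + (size_t)wo * Ho;
            const int wi = wo * st + kj - pad;
            if (wi < 0 || wi >= W) {
              std::memset(dst, 0, sizeof(double) * Ho);
              continue;
            }
            const double* src = plane + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * st + ki - pad;
              dst[ho] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
            }
          }
        }
        (void)P;
      }
    }
  }
}

// scatter-accumulate R [P, K] back into one image (adjoint of im2row)
static void row2im_one(const arma::mat& R, double* x, int H, int W, int C,
                       int kh, int kw, int st, int pad) {
  const int Ho = (H + 2 * pad - kh) / st + 1;
  const int Wo = (W + 2 * pad - kw) / st + 1;
  for (int c = 0; c < C; ++c) {
    double* plane = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* col = R.colptr(ki + kh * (kj + kw * c));
        if (st == 1) {
          const int lead = std::max(0, pad - ki);
          const int tail = std::min(Ho, H - ki + pad);
          if (tail <= lead) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo + kj - pad;
            if (wi < 0 || wi >= W) continue;
            const double* src = col + (size_t)wo * Ho + lead;
            double* dst = plane + (size_t)wi * H + (lead + ki - pad);
            const int len = tail - lead;
            for (int t = 0; t < len; ++t) dst[t] += src[t];
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * st + kj - pad;
            if (wi < 0 || wi >= W) continue;
            const double* src = col + (size_t)wo * Ho;
            double* dst = plane + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * st + ki - pad;
              if (hi >= 0 && hi < H) dst[hi] += src[ho];
            }
          }
        }
      }
    }
  }
}

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array [H,W,C,N]");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix wm,
                             int kh, int kw, int st, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = kh * kw * C;
  if (wm.nrow() != K) stop("weight rows mismatch im2row layout");
  const int Co = wm.ncol();
  const int Ho = (H + 2 * pad - kh) / st + 1;
  const int Wo = (W + 2 * pad - kw) / st + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");
  NumericVector y = make4(Ho, Wo, Co, N);
  arma::mat Wmat(wm.begin(), K, Co, false);
  arma::mat R((size_t)Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2row_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, st, pad, R);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * Co, (size_t)Ho * Wo, Co, false, true);
    Y = R * Wmat;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector dy, NumericMatrix wm,
                    int kh, int kw, int st, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dims4(dy);
  const int Ho = dd[0], Wo = dd[1], Co = dd[2];
  const int K = kh * kw * C;
  arma::mat Wmat(wm.begin(), K, Co, false);
  NumericVector dx = make4(H, W, C, N);
  arma::mat dW(K, Co, arma::fill::zeros);
  arma::mat R((size_t)Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(dy.begin() + (size_t)n * Ho * Wo * Co, (size_t)Ho * Wo, Co, false, true);
    im2row_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, st, pad, R);
    dW += R.t() * dY;
    arma::mat dR = dY * Wmat.t();  // [P, K]
    row2im_one(dR, dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, st, pad);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW));
}

// Transposed convolution: weight wm is [kh*kw*Co, Ci] (adjoint-conv layout).
// Output size Ho = (H-1)*st - 2*pad + kh.
// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericMatrix wm,
                              int co, int kh, int kw, int st, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Ci = d[2], N = d[3];
  const int K = kh * kw * co;
  if (wm.nrow() != K || wm.ncol() != Ci) stop("convT weight shape mismatch");
  const int Ho = (H - 1) * st - 2 * pad + kh;
  const int Wo = (W - 1) * st - 2 * pad + kw;
  if (Ho <= 0 || Wo <= 0) stop("degenerate convT output");
  NumericVector y = make4(Ho, Wo, co, N);
  arma::mat Wmat(wm.begin(), K, Ci, false);
  for (int n = 0; n < N; ++n) {
    arma::mat X(x.begin() + (size_t)n * H * W * Ci, (size_t)H * W, Ci, false, true);
    arma::mat R = X * Wmat.t();  // [H*W, K]
    row2im_one(R, y.begin() + (size_t)n * Ho * Wo * co, Ho, Wo, co, kh, kw, st, pad);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, NumericVector dy, NumericMatrix wm,
                     int co, int kh, int kw, int st, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Ci = d[2], N = d[3];
  IntegerVector dd = dims4(dy);
  const int Ho = dd[0], Wo = dd[1];
  const int K = kh * kw * co;
  arma::mat Wmat(wm.begin(), K, Ci, false);
  NumericVector dx = make4(H, W, Ci, N);
  arma::mat dW(K, Ci, arma::fill::zeros);
  arma::mat R((size_t)H * W, K);
  for (int n = 0; n < N; ++n) {
    im2row_one(dy.begin() + (size_t)n * Ho * Wo * co, Ho, Wo, co, kh, kw, st, pad, R);
    arma::mat X(x.begin() + (size_t)n * H * W * Ci, (size_t)H * W, Ci, false, true);
    dW += R.t() * X;
    arma::mat dX = R * Wmat;  // [H*W, Ci]
    std::copy(dX.begin(), dX.end(), dx.begin() + (size_t)n * H * W * Ci);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW));
}

// Depthwise convolution, stride 1, zero padding; w is [kh, kw, C].
// Tap-major loops accumulate contiguous column segments.
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w,
                               int kh, int kw, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  NumericVector y = make4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)(n * C + c) * H * W;
      const double* ker = w.begin() + (size_t)c * kh * kw;
      double* out = y.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double kv = ker[ki + kh * kj];
          if (kv == 0.0) continue;
          const int lead = std::max(0, pad - ki);
          const int tail = std::min(Ho, H - ki + pad);
          if (tail <= lead) continue;
          const int len = tail - lead;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo + kj - pad;
            if (wi < 0 || wi >= W) continue;
            const double* src = plane + (size_t)wi * H + (lead + ki - pad);
            double* dst = out + (size_t)wo * Ho + lead;
            for (int t = 0; t < len; ++t) dst[t] += kv * src[t];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector dy, NumericVector w,
                      int kh, int kw, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dims4(dy);
  const int Ho = dd[0], Wo = dd[1];
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw(Dimension(kh, kw, C));
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)(n * C + c) * H * W;
      const double* g = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      const double* ker = w.begin() + (size_t)c * kh * kw;
      double* dplane = dx.begin() + (size_t)(n * C + c) * H * W;
      double* dker = dw.begin() + (size_t)c * kh * kw;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double kv = ker[ki + kh * kj];
          double acc = 0.0;
          const int lead = std::max(0, pad - ki);
          const int tail = std::min(Ho, H - ki + pad);
          if (tail <= lead) continue;
          const int len = tail - lead;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo + kj - pad;
            if (wi < 0 || wi >= W) continue;
            const double* xs = plane + (size_t)wi * H + (lead + ki - pad);
            const double* gs = g + (size_t)wo * Ho + lead;
            double* dxs = dplane + (size_t)wi * H + (lead + ki - pad);
            for (int t = 0; t < len; ++t) {
              acc += gs[t] * xs[t];
              dxs[t] += kv * gs[t];
            }
          }
          dker[ki + kh * kj] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---- fused batch-norm helpers (per-channel over H,W,N of [H,W,C,N]) --------

// [[Rcpp::export]]
List cpp_channel_mean_var(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, sq = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) { s += p[t]; sq += p[t] * p[t]; }
    }
    const double m = s / (plane * N);
    mu[c] = m;
    var[c] = sq / (plane * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_affine_c(NumericVector x, NumericVector scale, NumericVector shift) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y = make4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * plane;
      double* q = y.begin() + ((size_t)n * C + c) * plane;
      const double a = scale[c], b = shift[c];
      for (size_t t = 0; t < plane; ++t) q[t] = p[t] * a + b;
    }
  }
  return y;
}

// training-mode batch-norm backward; xhat recomputed as x*istd - mu*istd
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector g, NumericVector gamma,
                NumericVector mu, NumericVector istd, bool training) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx = make4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    const double a = istd[c], b = -mu[c] * istd[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * plane;
      const double* gp = g.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        sg += gp[t];
        sgx += gp[t] * (xp[t] * a + b);
      }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double gam = gamma[c];
    if (training) {
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + ((size_t)n * C + c) * plane;
        const double* gp = g.begin() + ((size_t)n * C + c) * plane;
        double* dp = dx.begin() + ((size_t)n * C + c) * plane;
        const double k = gam * a / m;
        for (size_t t = 0; t < plane; ++t) {
          dp[t] = k * (m * gp[t] - sg - (xp[t] * a + b) * sgx);
        }
      }
    } else {
      const double k = gam * a;
      for (int n = 0; n < N; ++n) {
        const double* gp = g.begin() + ((size_t)n * C + c) * plane;
        double* dp = dx.begin() + ((size_t)n * C + c) * plane;
        for (size_t t = 0; t < plane; ++t) dp[t] = k * gp[t];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
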