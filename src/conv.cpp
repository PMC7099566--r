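// im2col / col2im for activations in (H, W, N, C) column-major layout.
// Convolution itself is then a single BLAS matrix multiply on the R side;
// these kernels only gather and scatter patch data. Row order of the patch
// matrix: oh fastest, then ow, then n, so the product with a (KH*KW*C, K)
// kernel matrix reshapes directly to (OH, OW, N, K).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector im2col_cpp(const NumericVector& x, const IntegerVector& xd,
                         const int KH, const int KW) {
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int OH = H - KH + 1, OW = W - KW + 1;
  const R_xlen_t rows = static_cast<R_xlen_t>(OH) * OW * N;
  NumericVector out(no_init(rows * KH * KW * C));
  out.attr("dim") = IntegerVector::create(rows, KH * KW * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < KW; ++q)
      for (int p = 0; p < KH; ++p) {
        double* col = op + (static_cast<R_xlen_t>(c) * KH * KW +
                            q * KH + p) * rows;
        for (int n = 0; n < N; ++n) {
          const double* xbase =
            xp + (static_cast<R_xlen_t>(c) * N + n) * H * W;
          for (int ow = 0; ow < OW; ++ow) {
            const double* src = xbase + (ow + q) * H + p;
            double* dst = col + (static_cast<R_xlen_t>(n) * OW + ow) * OH;
            for (int oh = 0; oh < OH; ++oh) dst[oh] = src[oh];
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericVector& cols, const IntegerVector& xd,
                         const int KH, const int KW) {
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int OH = H - KH + 1, OW = W - KW + 1;
  const R_xlen_t rows = static_cast<R_xlen_t>(OH) * OW * N;
  NumericVector x(static_cast<R_xlen_t>(H) * W * N * C);
  const double* cp = cols.begin();
  double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < KW; ++q)
      for (int p = 0; p < KH; ++p) {
        const double* col = cp + (static_cast<R_xlen_t>(c) * KH * KW +
                                  q * KH + p) * rows;
        for (int n = 0; n < N; ++n) {
          double* xbase = xp + (static_cast<R_xlen_t>(c) * N + n) * H * W;
          for (int ow = 0; ow < OW; ++ow) {
            const double* src = col + (static_cast<R_xlen_t>(n) * OW + ow) * OH;
            double* dst = xbase + (ow + q) * H + p;
            for (int oh = 0; oh < OH; ++oh) dst[oh] += src[oh];
          }
        }
      }
  return x;
}

// Batch-normalization cores. x is an (R, C) column-major matrix view of an
// activation array whose channel is the slowest-varying dimension, so each
// channel is one contiguous column block.

// [[Rcpp::export]]
List bn_fwd_cpp(const NumericVector& x, const int C,
                const NumericVector& gamma, const NumericVector& beta,
                const double eps) {
  const R_xlen_t R = x.size() / C;
  NumericVector out(no_init(x.size())), xhat(no_init(x.size()));
  NumericVector mu(C), inv_sd(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* col = xp + R * c;
    double s = 0.0;
    for (R_xlen_t i = 0; i < R; ++i) s += col[i];
    const double m = s / R;
    double v = 0.0;
    for (R_xlen_t i = 0; i < R; ++i) { const double d = col[i] - m; v += d * d; }
    v /= R;
    const double isd = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double* __restrict oc = out.begin() + R * c;
    double* __restrict hc = xhat.begin() + R * c;
    for (R_xlen_t i = 0; i < R; ++i) {
      const double h = (col[i] - m) * isd;
      hc[i] = h;
      oc[i] = g * h + b;
    }
    mu[c] = m; var[c] = v; inv_sd[c] = isd;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
NumericVector bn_infer_cpp(const NumericVector& x, const int C,
                           const NumericVector& mean, const NumericVector& var,
                           const NumericVector& gamma, const NumericVector& beta,
                           const double eps) {
  const R_xlen_t R = x.size() / C;
  NumericVector out(no_init(x.size()));
  for (int c = 0; c < C; ++c) {
    const double isd = 1.0 / std::sqrt(var[c] + eps);
    const double m = mean[c], g = gamma[c], b = beta[c];
    const double* col = x.begin() + R * c;
    double* __restrict oc = out.begin() + R * c;
    for (R_xlen_t i = 0; i < R; ++i) oc[i] = g * (col[i] - m) * isd + b;
  }
  return out;
}

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericVector& dout, const NumericVector& xhat,
                const NumericVector& inv_sd, const NumericVector& gamma) {
  const int C = gamma.size();
  const R_xlen_t R = dout.size() / C;
  NumericVector dx(no_init(dout.size())), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.begin() + R * c;
    const double* hc = xhat.begin() + R * c;
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < R; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], isd = inv_sd[c];
    const double mh = sb / R;          // mean of dxhat / gamma
    const double mhh = sg / R;         // mean of dxhat * xhat / gamma
    double* __restrict xc = dx.begin() + R * c;
    for (R_xlen_t i = 0; i < R; ++i)
      xc[i] = isd * g * (dc[i] - mh - hc[i] * mhh);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 average pooling on (H, W, N, C) arrays, stride 2.

// [[Rcpp::export]]
NumericVector pool_fwd_cpp(const NumericVector& x, const IntegerVector& xd) {
  const int H = xd[0], W = xd[1];
  const R_xlen_t planes = static_cast<R_xlen_t>(xd[2]) * xd[3];
  const int OH = H / 2, OW = W / 2;
  NumericVector out(no_init(static_cast<R_xlen_t>(OH) * OW * planes));
  for (R_xlen_t pl = 0; pl < planes; ++pl) {
    const double* xp = x.begin() + pl * H * W;
    double* __restrict op = out.begin() + pl * OH * OW;
    for (int ow = 0; ow < OW; ++ow) {
      const double* c0 = xp + 2 * ow * H;
      const double* c1 = c0 + H;
      double* oc = op + ow * OH;
      for (int oh = 0; oh < OH; ++oh)
        oc[oh] = 0.25 * (c0[2 * oh] + c0[2 * oh + 1] +
                         c1[2 * oh] + c1[2 * oh + 1]);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(const NumericVector& dout, const IntegerVector& od) {
  const int OH = od[0], OW = od[1];
  const R_xlen_t planes = static_cast<R_xlen_t>(od[2]) * od[3];
  const int H = OH * 2, W = OW * 2;
  NumericVector dx(no_init(static_cast<R_xlen_t>(H) * W * planes));
  for (R_xlen_t pl = 0; pl < planes; ++pl) {
    const double* dp = dout.begin() + pl * OH * OW;
    double* __restrict xp = dx.begin() + pl * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      const double* dc = dp + ow * OH;
      double* x0 = xp + 2 * ow * H;
      double* x1 = x0 + H;
      for (int oh = 0; oh < OH; ++oh) {
        const double g = 0.25 * dc[oh];
        x0[2 * oh] = g; x0[2 * oh + 1] = g;
        x1[2 * oh] = g; x1[2 * oh + 1] = g;
      }
    }
  }
  return dx;
}

// Elementwise logistic sigmoid and its backward pass. IEEE semantics give
// exact saturation (overflowed exp -> Inf -> 0) without error.

// [[Rcpp::export]]
NumericVector sigmoid_cpp(const NumericVector& x) {
  NumericVector out(no_init(x.size()));
  const double* xp = x.begin();
  double* __restrict op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector sigmoid_bwd_cpp(const NumericVector& dout,
                              const NumericVector& out) {
  NumericVector dx(no_init(dout.size()));
  const double* dp = dout.begin();
  const double* op = out.begin();
  double* __restrict xp = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = dp[i] * op[i] * (1.0 - op[i]);
  return dx;
}
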