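#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix helpers for strided, zero-padded 2D convolution on a single
// H x W x C sample stored column-major (R array order: h fastest, then w,
// then channel).
//
// im2col column j = oh + ow * Ho   (output position, oh fastest)
// im2col row    r = kh + kw * k + c * k * k   (kernel offset, kh fastest)
//
// so that  crossprod(cols, Wmat)  with Wmat = matrix(W[k,k,Cin,Cout]) gives
// the conv output in the same column-major layout.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1)
    stop("im2col: kernel/stride/pad plan yields empty output");
  NumericMatrix cols(k * k * C, Ho * Wo);
  double *pc = cols.begin();
  const double *px = x.begin();
  const int nrow = k * k * C;
  for (int ow = 0; ow < Wo; ++ow) {
    const int w0 = ow * stride - pad;
    for (int oh = 0; oh < Ho; ++oh) {
      const int h0 = oh * stride - pad;
      double *col = pc + (size_t)(oh + (size_t)ow * Ho) * nrow;
      for (int c = 0; c < C; ++c) {
        const double *xc = px + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          const bool win = (wi >= 0 && wi < W);
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            double v = 0.0;
            if (win && hi >= 0 && hi < H) v = xc[hi + (size_t)wi * H];
            col[kh + k * (kw + k * c)] = v;
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add inverse of im2col_cpp: accumulates patch columns back onto the
// H x W x C grid. Used for conv input-gradients and transposed-conv forward.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (cols.nrow() != k * k * C || cols.ncol() != Ho * Wo)
    stop("col2im: patch matrix dimensions do not match the geometry");
  NumericVector out((size_t)H * W * C);
  double *po = out.begin();
  const double *pc = cols.begin();
  const int nrow = k * k * C;
  for (int ow = 0; ow < Wo; ++ow) {
    const int w0 = ow * stride - pad;
    for (int oh = 0; oh < Ho; ++oh) {
      const int h0 = oh * stride - pad;
      const double *col = pc + (size_t)(oh + (size_t)ow * Ho) * nrow;
      for (int c = 0; c < C; ++c) {
        double *oc = po + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            oc[hi + (size_t)wi * H] += col[kh + k * (kw + k * c)];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Fused Adam update for one parameter tensor: single pass, bias-corrected.
// Returns updated copies of (param, m, v).

// [[Rcpp::export]]
List adam_update_cpp(NumericVector p, NumericVector g,
                     NumericVector m, NumericVector v,
                     double lr, double b1, double b2, double eps, int t) {
  R_xlen_t n = p.size();
  NumericVector p2 = clone(p), m2 = clone(m), v2 = clone(v);
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = b1 * m2[i] + (1.0 - b1) * gi;
    const double vi = b2 * v2[i] + (1.0 - b2) * gi * gi;
    m2[i] = mi; v2[i] = vi;
    p2[i] = p2[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
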