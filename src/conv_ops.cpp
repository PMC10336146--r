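#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix assembly/scatter for the convolution layers. Only the
// memory reordering lives here; the matrix products stay in R (BLAS).
//
// Layouts (column-major, first index fastest):
//   2-D maps:  (H, W, B, C)   frequency, time, batch, channel
//   1-D seqs:  (T, B, C)
// Patch matrix columns are ordered channel-fastest within an offset
// block; offsets enumerate ky fastest, then kx.

// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector xp, int Hp, int Wp, int B, int C,
                           int kh, int kw, int sh, int sw,
                           int Hout, int Wout) {
  const double *x = xp.begin();
  const R_xlen_t rows = (R_xlen_t)Hout * Wout * B;
  NumericMatrix out(rows, (R_xlen_t)kh * kw * C);
  double *o = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)Hp * Wp;
  for (int kx = 0; kx < kw; ++kx) {
    for (int ky = 0; ky < kh; ++ky) {
      const int off = kx * kh + ky;
      for (int c = 0; c < C; ++c) {
        double *col = o + ((R_xlen_t)off * C + c) * rows;
        for (int b = 0; b < B; ++b) {
          const double *src = x + ((R_xlen_t)c * B + b) * planeHW;
          for (int w = 0; w < Wout; ++w) {
            const double *sp = src + (R_xlen_t)(kx + w * sw) * Hp + ky;
            double *dp = col + ((R_xlen_t)b * Wout + w) * Hout;
            for (int h = 0; h < Hout; ++h) dp[h] = sp[(R_xlen_t)h * sh];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix dXc, int Hp, int Wp, int B, int C,
                           int kh, int kw, int sh, int sw,
                           int Hout, int Wout) {
  NumericVector dxp((R_xlen_t)Hp * Wp * B * C);
  double *x = dxp.begin();
  const double *g = dXc.begin();
  const R_xlen_t rows = (R_xlen_t)Hout * Wout * B;
  const R_xlen_t planeHW = (R_xlen_t)Hp * Wp;
  for (int kx = 0; kx < kw; ++kx) {
    for (int ky = 0; ky < kh; ++ky) {
      const int off = kx * kh + ky;
      for (int c = 0; c < C; ++c) {
        const double *col = g + ((R_xlen_t)off * C + c) * rows;
        for (int b = 0; b < B; ++b) {
          double *dst = x + ((R_xlen_t)c * B + b) * planeHW;
          for (int w = 0; w < Wout; ++w) {
            double *dp = dst + (R_xlen_t)(kx + w * sw) * Hp + ky;
            const double *sp = col + ((R_xlen_t)b * Wout + w) * Hout;
            for (int h = 0; h < Hout; ++h) dp[(R_xlen_t)h * sh] += sp[h];
          }
        }
      }
    }
  }
  dxp.attr("dim") = IntegerVector::create(Hp, Wp, B, C);
  return dxp;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(NumericVector xp, int Tp, int B, int C,
                           int k, int T) {
  const double *x = xp.begin();
  const R_xlen_t rows = (R_xlen_t)T * B;
  NumericMatrix out(rows, (R_xlen_t)k * C);
  double *o = out.begin();
  for (int kt = 0; kt < k; ++kt) {
    for (int c = 0; c < C; ++c) {
      double *col = o + ((R_xlen_t)kt * C + c) * rows;
      for (int b = 0; b < B; ++b) {
        const double *src = x + ((R_xlen_t)c * B + b) * Tp + kt;
        double *dp = col + (R_xlen_t)b * T;
        for (int t = 0; t < T; ++t) dp[t] = src[t];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im1d(NumericMatrix dXc, int Tp, int B, int C,
                           int k, int T) {
  NumericVector dxp((R_xlen_t)Tp * B * C);
  double *x = dxp.begin();
  const double *g = dXc.begin();
  const R_xlen_t rows = (R_xlen_t)T * B;
  for (int kt = 0; kt < k; ++kt) {
    for (int c = 0; c < C; ++c) {
      const double *col = g + ((R_xlen_t)kt * C + c) * rows;
      for (int b = 0; b < B; ++b) {
        double *dst = x + ((R_xlen_t)c * B + b) * Tp + kt;
        const double *sp = col + (R_xlen_t)b * T;
        for (int t = 0; t < T; ++t) dst[t] += sp[t];
      }
    }
  }
  dxp.attr("dim") = IntegerVector::create(Tp, B, C);
  return dxp;
}

// 2x2 max pooling forward: returns pooled map plus the argmax index
// (0..3, ordering: top-left, bottom-left, top-right, bottom-right).
// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t n = (R_xlen_t)Ho * Wo * B * C;
  NumericVector out(n);
  IntegerVector which(n);
  const double *xv = x.begin();
  double *o = out.begin();
  int *wv = which.begin();
  R_xlen_t i = 0;
  for (R_xlen_t bc = 0; bc < (R_xlen_t)B * C; ++bc) {
    const double *plane = xv + bc * H * W;
    for (int w = 0; w < Wo; ++w) {
      const double *c0 = plane + (R_xlen_t)(2 * w) * H;
      const double *c1 = plane + (R_xlen_t)(2 * w + 1) * H;
      for (int h = 0; h < Ho; ++h, ++i) {
        double v = c0[2 * h];
        int a = 0;
        if (c0[2 * h + 1] > v) { v = c0[2 * h + 1]; a = 1; }
        if (c1[2 * h] > v) { v = c1[2 * h]; a = 2; }
        if (c1[2 * h + 1] > v) { v = c1[2 * h + 1]; a = 3; }
        o[i] = v;
        wv[i] = a;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d_backward(NumericVector dout, IntegerVector which,
                                     int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * B * C);
  double *d = dx.begin();
  const double *g = dout.begin();
  const int *wv = which.begin();
  R_xlen_t i = 0;
  for (R_xlen_t bc = 0; bc < (R_xlen_t)B * C; ++bc) {
    double *plane = d + bc * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h, ++i) {
        const int a = wv[i];
        const R_xlen_t col = (R_xlen_t)(2 * w + (a >> 1)) * H;
        plane[col + 2 * h + (a & 1)] += g[i];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}
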