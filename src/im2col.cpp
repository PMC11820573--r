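// Patch-extraction kernels for the convolution layers of the network
// engine.  Tensors are R arrays with dim (H, W, C, N); patch matrices
// have one row per output pixel (h fastest, then w, then n) and one
// column per (kernel offset, channel) pair with column = o*C + c,
// o = dh + k*dw.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out((R_xlen_t)Ho * Wo * N, (R_xlen_t)C * k * k);
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int dw = 0; dw < k; ++dw) {
    for (int dh = 0; dh < k; ++dh) {
      int o = dh + k * dw;
      for (int c = 0; c < C; ++c) {
        R_xlen_t col = (R_xlen_t)o * C + c;
        double* dst = op + col * nrow;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < Wo; ++w) {
            int iw = w * stride + dw - pad;
            R_xlen_t rbase = (R_xlen_t)Ho * (w + (R_xlen_t)Wo * n);
            if (iw < 0 || iw >= W) {
              for (int h = 0; h < Ho; ++h) dst[rbase + h] = 0.0;
              continue;
            }
            const double* src =
                xp + (R_xlen_t)H * (iw + (R_xlen_t)W *
                                    (c + (R_xlen_t)C * n));
            for (int h = 0; h < Ho; ++h) {
              int ih = h * stride + dh - pad;
              dst[rbase + h] = (ih >= 0 && ih < H) ? src[ih] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int dw = 0; dw < k; ++dw) {
    for (int dh = 0; dh < k; ++dh) {
      int o = dh + k * dw;
      for (int c = 0; c < C; ++c) {
        R_xlen_t col = (R_xlen_t)o * C + c;
        const double* src = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < Wo; ++w) {
            int iw = w * stride + dw - pad;
            if (iw < 0 || iw >= W) continue;
            R_xlen_t rbase = (R_xlen_t)Ho * (w + (R_xlen_t)Wo * n);
            double* dst =
                xp + (R_xlen_t)H * (iw + (R_xlen_t)W *
                                    (c + (R_xlen_t)C * n));
            for (int h = 0; h < Ho; ++h) {
              int ih = h * stride + dh - pad;
              if (ih >= 0 && ih < H) dst[ih] += src[rbase + h];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}
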