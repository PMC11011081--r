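#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major (C, H, W, N) arrays flattened to vectors.
// im2col rows are ordered channel-fastest, then kernel row, then kernel
// column; columns are ordered (ho, wo, n) column-major so the gemm result
// reshapes directly to a (Cout, Ho, Wo, N) array.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo * N);
  double *po = out.begin();
  double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *pc = po + col * (R_xlen_t)(C * k * k);
        for (int kj = 0; kj < k; ++kj) {
          int iw = wo * stride + kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            int ih = ho * stride + ki - pad;
            double *dst = pc + (R_xlen_t)C * (ki + k * kj);
            if (ih >= 0 && ih < H && iw >= 0 && iw < W) {
              double *src = px + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
              memcpy(dst, src, sizeof(double) * C);
            } else {
              memset(dst, 0, sizeof(double) * C);
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *px = x.begin();
  double *po = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *pc = po + col * (R_xlen_t)(C * k * k);
        for (int kj = 0; kj < k; ++kj) {
          int iw = wo * stride + kj - pad;
          if (iw < 0 || iw >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int ih = ho * stride + ki - pad;
            if (ih < 0 || ih >= H) continue;
            double *src = pc + (R_xlen_t)C * (ki + k * kj);
            double *dst = px + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}
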