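#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as 4-D arrays with dims (H, W, N, C), column-major.
// im2col for a 3x3 same-padded convolution: output matrix has one row per
// spatial position per image (r = h + H*(w + W*n)) and one column per
// (kh, kw, c) tap (j = kh + 3*kw + 9*c). Padding reads as zero.

// [[Rcpp::export(name = ".im2col3x3")]]
NumericMatrix im2col3x3(NumericVector x, int H, int W, int N, int C) {
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericMatrix out(nrow, 9 * C);
  const double* px = x.begin();
  double* pout = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int j = kh + 3 * kw + 9 * c;
        double* col = pout + (R_xlen_t)j * nrow;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t base_in = ((R_xlen_t)c * N + n) * W;
          const R_xlen_t base_out = (R_xlen_t)n * W;
          for (int w = 0; w < W; ++w) {
            const int w2 = w + kw - 1;
            double* dst = col + (base_out + w) * H;
            if (w2 < 0 || w2 >= W) {
              for (int h = 0; h < H; ++h) dst[h] = 0.0;
              continue;
            }
            const double* src = px + (base_in + w2) * H;
            for (int h = 0; h < H; ++h) {
              const int h2 = h + kh - 1;
              dst[h] = (h2 < 0 || h2 >= H) ? 0.0 : src[h2];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3x3: scatter-add a (H*W*N) x (9*C) gradient matrix back
// onto the (H, W, N, C) input layout.

// [[Rcpp::export(name = ".col2im3x3")]]
NumericVector col2im3x3(NumericMatrix cols, int H, int W, int N, int C) {
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double* pc = cols.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int j = kh + 3 * kw + 9 * c;
        const double* col = pc + (R_xlen_t)j * nrow;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t base_out = ((R_xlen_t)c * N + n) * W;
          const R_xlen_t base_in = (R_xlen_t)n * W;
          for (int w = 0; w < W; ++w) {
            const int w2 = w + kw - 1;
            if (w2 < 0 || w2 >= W) continue;
            const double* src = col + (base_in + w) * H;
            double* dst = po + (base_out + w2) * H;
            for (int h = 0; h < H; ++h) {
              const int h2 = h + kh - 1;
              if (h2 >= 0 && h2 < H) dst[h2] += src[h];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}
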