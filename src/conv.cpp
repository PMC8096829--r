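#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for convolution-as-matrix-multiply.
//
// input:  H x W x C array (R column-major, first index fastest)
// output: (oh * ow) x (k * k * C) matrix; patch index p = oy + oh * ox,
//         column index q = ky + k * kx + k * k * c. Out-of-canvas taps
//         (zero padding) contribute zeros.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector input, int H, int W, int C,
                         int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(oh * ow, k * k * C);
  const double *in = input.begin();
  double *o = out.begin();
  const int np = oh * ow;
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + k * kx + k * k * c;
        double *ocol = o + (size_t)col * np;
        for (int ox = 0; ox < ow; ++ox) {
          const int x = ox * stride + kx - pad;
          if (x < 0 || x >= W) continue;
          const double *icol = in + (size_t)c * H * W + (size_t)x * H;
          for (int oy = 0; oy < oh; ++oy) {
            const int y = oy * stride + ky - pad;
            if (y < 0 || y >= H) continue;
            ocol[oy + oh * ox] = icol[y];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector out(H * W * C);
  const int np = oh * ow;
  const double *ci = cols.begin();
  double *o = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + k * kx + k * k * c;
        const double *ccol = ci + (size_t)col * np;
        for (int ox = 0; ox < ow; ++ox) {
          const int x = ox * stride + kx - pad;
          if (x < 0 || x >= W) continue;
          double *ocol = o + (size_t)c * H * W + (size_t)x * H;
          for (int oy = 0; oy < oh; ++oy) {
            const int y = oy * stride + ky - pad;
            if (y < 0 || y >= H) continue;
            ocol[y] += ccol[oy + oh * ox];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
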