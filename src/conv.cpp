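#include <Rcpp.h>
using namespace Rcpp;

// Image batches are R arrays of dim (H, W, C, N), column-major. The
// convolutions are evaluated as im2col + GEMM: these helpers only gather
// and scatter patches, the matrix products run in R's BLAS.

static inline int out_len(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Patch matrix of dim (k*k*Cin) x (Ho*Wo*N); row index runs (kh, kw, ci),
// column index runs (ho, wo, n), both fastest-first. Out-of-range source
// pixels (zero padding) stay 0.
// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Ho = out_len(H, k, stride, pad), Wo = out_len(W, k, stride, pad);
  const int rows = k * k * Ci;
  NumericMatrix cols(rows, Ho * Wo * N);
  const double *xp = x.begin();
  double *cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + static_cast<R_xlen_t>(n) * H * W * Ci;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        double *col = cp + static_cast<R_xlen_t>(rows) *
          (ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * n));
        for (int ci = 0; ci < Ci; ++ci) {
          const double *xc = xn + static_cast<R_xlen_t>(ci) * H * W;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = w0 + kw;
            double *dst = col + ci * k * k + kw * k;
            if (wi < 0 || wi >= W) {
              for (int kh = 0; kh < k; ++kh) dst[kh] = 0.0;
              continue;
            }
            const double *src = xc + static_cast<R_xlen_t>(wi) * H;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = h0 + kh;
              dst[kh] = (hi < 0 || hi >= H) ? 0.0 : src[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-adds a patch-gradient matrix back onto the
// input shape (H, W, Ci, N).
// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im(NumericMatrix dcols, IntegerVector xdim, int k,
                     int stride, int pad) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int Ho = out_len(H, k, stride, pad), Wo = out_len(W, k, stride, pad);
  const int rows = k * k * Ci;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Ci * N);
  gx.attr("dim") = xdim;
  const double *cp = dcols.begin();
  double *gp = gx.begin();
  for (int n = 0; n < N; ++n) {
    double *gn = gp + static_cast<R_xlen_t>(n) * H * W * Ci;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        const double *col = cp + static_cast<R_xlen_t>(rows) *
          (ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * n));
        for (int ci = 0; ci < Ci; ++ci) {
          double *gc = gn + static_cast<R_xlen_t>(ci) * H * W;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = w0 + kw;
            if (wi < 0 || wi >= W) continue;
            double *dst = gc + static_cast<R_xlen_t>(wi) * H;
            const double *src = col + ci * k * k + kw * k;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = h0 + kh;
              if (hi >= 0 && hi < H) dst[hi] += src[kh];
            }
          }
        }
      }
    }
  }
  return gx;
}
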