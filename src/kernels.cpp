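// Inner kernels of the CNN layer library: im2col/col2im for standard
// convolutions (GEMM itself stays in R/BLAS), direct depthwise convolution
// forward/backward, and a dim-3/4 permutation used to assemble GEMM output
// into (H, W, C, N) tensors. Zero padding is implicit: out-of-bounds reads
// contribute 0, out-of-bounds writes are dropped. Bounds are hoisted out of
// the inner loops by precomputing the valid output index ranges per kernel
// offset.

#include <Rcpp.h>
using namespace Rcpp;

static inline int outSize(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// first output index o with o*stride + off >= 0
static inline int loIdx(int off, int stride) {
  return off >= 0 ? 0 : (-off + stride - 1) / stride;
}

// one past the last output index o with o*stride + off < n
static inline int hiIdx(int off, int stride, int n, int nOut) {
  int h = (n - 1 - off) / stride + 1;
  if (h > nOut) h = nOut;
  if (h < 0) h = 0;
  return h;
}

// x: (H, W, C, N) column-major; result: (Ho*Wo*N) x (k*k*C),
// row index r = ho + Ho*wo + Ho*Wo*n, column index (o-1)*C + c with
// o = (kx-1)*k + ky (ky fastest), matching the R-side reshapes.
// [[Rcpp::export]]
NumericMatrix im2colCpp(NumericVector x, IntegerVector dims, int k,
                        int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  const double *px = x.begin();
  NumericMatrix P(Ho * Wo * N, k * k * C);
  double *pp = P.begin();
  const int nrow = Ho * Wo * N;
  for (int kx = 0; kx < k; ++kx) {
    const int offW = kx - pad;
    const int wo0 = loIdx(offW, stride), wo1 = hiIdx(offW, stride, W, Wo);
    for (int ky = 0; ky < k; ++ky) {
      const int offH = ky - pad;
      const int ho0 = loIdx(offH, stride), ho1 = hiIdx(offH, stride, H, Ho);
      const int o = kx * k + ky;
      for (int c = 0; c < C; ++c) {
        double *col = pp + (size_t)(o * C + c) * nrow;
        for (int n = 0; n < N; ++n) {
          const double *xc = px + (size_t)(n * C + c) * H * W;
          double *base = col + (size_t)n * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            double *dst = base + (size_t)wo * Ho;
            if (wo < wo0 || wo >= wo1) {
              std::fill(dst, dst + Ho, 0.0);
              continue;
            }
            const double *src = xc + (size_t)(wo * stride + offW) * H;
            for (int ho = 0; ho < ho0; ++ho) dst[ho] = 0.0;
            if (stride == 1) {
              for (int ho = ho0; ho < ho1; ++ho) dst[ho] = src[ho + offH];
            } else {
              for (int ho = ho0; ho < ho1; ++ho) {
                dst[ho] = src[ho * stride + offH];
              }
            }
            for (int ho = ho1; ho < Ho; ++ho) dst[ho] = 0.0;
          }
        }
      }
    }
  }
  return P;
}

// scatter-add the patch-gradient matrix back onto the input grid
// [[Rcpp::export]]
NumericVector col2imCpp(NumericMatrix dP, IntegerVector dims, int k,
                        int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = dims;
  double *pdx = dx.begin();
  const double *pp = dP.begin();
  const int nrow = Ho * Wo * N;
  for (int kx = 0; kx < k; ++kx) {
    const int offW = kx - pad;
    const int wo0 = loIdx(offW, stride), wo1 = hiIdx(offW, stride, W, Wo);
    for (int ky = 0; ky < k; ++ky) {
      const int offH = ky - pad;
      const int ho0 = loIdx(offH, stride), ho1 = hiIdx(offH, stride, H, Ho);
      const int o = kx * k + ky;
      for (int c = 0; c < C; ++c) {
        const double *col = pp + (size_t)(o * C + c) * nrow;
        for (int n = 0; n < N; ++n) {
          double *xc = pdx + (size_t)(n * C + c) * H * W;
          const double *base = col + (size_t)n * Ho * Wo;
          for (int wo = wo0; wo < wo1; ++wo) {
            const double *src = base + (size_t)wo * Ho;
            double *dst = xc + (size_t)(wo * stride + offW) * H;
            if (stride == 1) {
              for (int ho = ho0; ho < ho1; ++ho) dst[ho + offH] += src[ho];
            } else {
              for (int ho = ho0; ho < ho1; ++ho) {
                dst[ho * stride + offH] += src[ho];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// depthwise conv forward; W is (k*k) x C with row o = kx*k + ky, b length C
// [[Rcpp::export]]
NumericVector dwConvFwdCpp(NumericVector x, IntegerVector dims,
                           NumericMatrix Wm, NumericVector b, int k,
                           int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double *po = out.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = px + (size_t)(n * C + c) * H * W;
      double *oc = po + (size_t)(n * C + c) * Ho * Wo;
      std::fill(oc, oc + (size_t)Ho * Wo, b[c]);
      for (int kx = 0; kx < k; ++kx) {
        const int offW = kx - pad;
        const int wo0 = loIdx(offW, stride), wo1 = hiIdx(offW, stride, W, Wo);
        for (int ky = 0; ky < k; ++ky) {
          const int offH = ky - pad;
          const int ho0 = loIdx(offH, stride), ho1 = hiIdx(offH, stride, H, Ho);
          const double w = Wm(kx * k + ky, c);
          for (int wo = wo0; wo < wo1; ++wo) {
            const double *src = xc + (size_t)(wo * stride + offW) * H + offH;
            double *dst = oc + (size_t)wo * Ho;
            if (stride == 1) {
              for (int ho = ho0; ho < ho1; ++ho) dst[ho] += w * src[ho];
            } else {
              for (int ho = ho0; ho < ho1; ++ho) {
                dst[ho] += w * src[ho * stride];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// depthwise conv backward: input gradient, weight gradient, bias gradient
// [[Rcpp::export]]
List dwConvBwdCpp(NumericVector x, IntegerVector dims, NumericVector dy,
                  NumericMatrix Wm, int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = dims;
  NumericMatrix dW(k * k, C);
  NumericVector db(C);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = px + (size_t)(n * C + c) * H * W;
      const double *gc = pdy + (size_t)(n * C + c) * Ho * Wo;
      double *dxc = pdx + (size_t)(n * C + c) * H * W;
      double accb = 0.0;
      const size_t nOut = (size_t)Ho * Wo;
      for (size_t i = 0; i < nOut; ++i) accb += gc[i];
      db[c] += accb;
      for (int kx = 0; kx < k; ++kx) {
        const int offW = kx - pad;
        const int wo0 = loIdx(offW, stride), wo1 = hiIdx(offW, stride, W, Wo);
        for (int ky = 0; ky < k; ++ky) {
          const int offH = ky - pad;
          const int ho0 = loIdx(offH, stride), ho1 = hiIdx(offH, stride, H, Ho);
          const double w = Wm(kx * k + ky, c);
          double accw = 0.0;
          for (int wo = wo0; wo < wo1; ++wo) {
            const double *xcol = xc + (size_t)(wo * stride + offW) * H + offH;
            double *dxcol = dxc + (size_t)(wo * stride + offW) * H + offH;
            const double *g = gc + (size_t)wo * Ho;
            if (stride == 1) {
              for (int ho = ho0; ho < ho1; ++ho) {
                accw += g[ho] * xcol[ho];
                dxcol[ho] += g[ho] * w;
              }
            } else {
              for (int ho = ho0; ho < ho1; ++ho) {
                accw += g[ho] * xcol[ho * stride];
                dxcol[ho * stride] += g[ho] * w;
              }
            }
          }
          dW(kx * k + ky, c) += accw;
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// permute (H, W, A, B) -> (H, W, B, A); self-inverse up to swapped dims
// [[Rcpp::export]]
NumericVector permute34Cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], A = dims[2], B = dims[3];
  NumericVector out((size_t)H * W * A * B);
  out.attr("dim") = IntegerVector::create(H, W, B, A);
  const double *px = x.begin();
  double *po = out.begin();
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    for (int a = 0; a < A; ++a) {
      const double *src = px + ((size_t)b * A + a) * HW;
      double *dst = po + ((size_t)a * B + b) * HW;
      std::copy(src, src + HW, dst);
    }
  }
  return out;
}
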