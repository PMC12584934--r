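#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Kernels backing the 3D convolutional blocks of the air-cavity U-Net.
// Feature maps are R arrays of dim (D, H, W, C), column-major. im2col
// unrolls a k x k x k neighbourhood (zero padding `pad`, stride 1) of
// every voxel into one row; column order is depth-offset fastest, then
// height, width, and channel slowest. Convolution forward is then a
// single GEMM with a (k^3*C_in) x C_out weight matrix done in R/BLAS.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dim4, int k,
                          int pad) {
  const int D = dim4[0], H = dim4[1], W = dim4[2], C = dim4[3];
  const R_xlen_t n = (R_xlen_t)D * H * W;
  NumericMatrix cols(n, (R_xlen_t)k * k * k * C);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)c * D * H * W;
    for (int ow = 0; ow < k; ++ow)
      for (int oh = 0; oh < k; ++oh)
        for (int od = 0; od < k; ++od) {
          R_xlen_t col = ((R_xlen_t)c * k + ow) * k * k + (R_xlen_t)oh * k + od;
          double *dst = &cols(0, col);
          const int sh0 = od - pad;  // shift along d
          const int dlo = std::max(0, -sh0), dhi = std::min(D, D - sh0);
          for (int w = 0; w < W; ++w) {
            int sw = w + ow - pad;
            for (int h = 0; h < H; ++h) {
              int sh = h + oh - pad;
              R_xlen_t base = (R_xlen_t)w * H * D + (R_xlen_t)h * D;
              if (sw < 0 || sw >= W || sh < 0 || sh >= H) {
                std::memset(dst + base, 0, D * sizeof(double));
                continue;
              }
              const double *src = xc + (R_xlen_t)sw * H * D + (R_xlen_t)sh * D;
              for (int d = 0; d < dlo; ++d) dst[base + d] = 0.0;
              if (dhi > dlo)
                std::memcpy(dst + base + dlo, src + dlo + sh0,
                            (dhi - dlo) * sizeof(double));
              for (int d = dhi; d < D; ++d) dst[base + d] = 0.0;
            }
          }
        }
  }
  return cols;
}

// Adjoint of im2col: scatter-add rows back into an array of dim4.
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix cols, IntegerVector dim4, int k,
                          int pad) {
  const int D = dim4[0], H = dim4[1], W = dim4[2], C = dim4[3];
  NumericVector x((R_xlen_t)D * H * W * C);
  double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = xp + (R_xlen_t)c * D * H * W;
    for (int ow = 0; ow < k; ++ow)
      for (int oh = 0; oh < k; ++oh)
        for (int od = 0; od < k; ++od) {
          R_xlen_t col = ((R_xlen_t)c * k + ow) * k * k + (R_xlen_t)oh * k + od;
          const double *src = &cols(0, col);
          const int sh0 = od - pad;
          const int dlo = std::max(0, -sh0), dhi = std::min(D, D - sh0);
          for (int w = 0; w < W; ++w) {
            int sw = w + ow - pad;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + oh - pad;
              if (sh < 0 || sh >= H) continue;
              R_xlen_t base = (R_xlen_t)w * H * D + (R_xlen_t)h * D;
              double *dstc = xc + (R_xlen_t)sw * H * D + (R_xlen_t)sh * D;
              const double *s = src + base;
              double *dd = dstc + sh0;
              for (int d = dlo; d < dhi; ++d) dd[d] += s[d];
            }
          }
        }
  }
  return x;
}

// 2x2x2 max pooling (stride 2). Returns pooled values and the 0-based
// linear index of each argmax for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3(NumericVector x, IntegerVector dim4) {
  const int D = dim4[0], H = dim4[1], W = dim4[2], C = dim4[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Do * Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Do * Ho * Wo * C);
  const double *xp = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    R_xlen_t cbase = (R_xlen_t)c * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int ow = 0; ow < 2; ++ow)
            for (int oh = 0; oh < 2; ++oh)
              for (int od = 0; od < 2; ++od) {
                R_xlen_t idx = cbase + (R_xlen_t)(2 * w + ow) * H * D +
                               (R_xlen_t)(2 * h + oh) * D + (2 * d + od);
                if (xp[idx] > best) {
                  best = xp[idx];
                  bidx = idx;
                }
              }
          y[o] = best;
          arg[o] = (int)bidx;
          ++o;
        }
  }
  return List::create(Named("values") = y, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_backward(NumericVector dy, IntegerVector argmax,
                                    R_xlen_t size_x) {
  NumericVector dx(size_x);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// Transposed convolution, kernel 2 stride 2 (non-overlapping blocks).
// ycols is (D*H*W_in) x (Cout*8) with block-offset order od,oh,ow fastest
// within each output channel; scatter into dim (2D, 2H, 2W, Cout).
// [[Rcpp::export]]
NumericVector cpp_upsample2_scatter(NumericMatrix ycols, IntegerVector dim_in,
                                    int cout) {
  const int D = dim_in[0], H = dim_in[1], W = dim_in[2];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Do * Ho * Wo * cout);
  double *yp = y.begin();
  for (int c = 0; c < cout; ++c) {
    double *yc = yp + (R_xlen_t)c * Do * Ho * Wo;
    for (int ow = 0; ow < 2; ++ow)
      for (int oh = 0; oh < 2; ++oh)
        for (int od = 0; od < 2; ++od) {
          R_xlen_t col = (R_xlen_t)c * 8 + ow * 4 + oh * 2 + od;
          const double *src = &ycols(0, col);
          R_xlen_t r = 0;
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              for (int d = 0; d < D; ++d) {
                yc[(R_xlen_t)(2 * w + ow) * Ho * Do +
                   (R_xlen_t)(2 * h + oh) * Do + (2 * d + od)] = src[r++];
              }
        }
  }
  return y;
}

// Gather adjoint of cpp_upsample2_scatter for the backward pass.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2_gather(NumericVector dy, IntegerVector dim_in,
                                   int cout) {
  const int D = dim_in[0], H = dim_in[1], W = dim_in[2];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericMatrix cols((R_xlen_t)D * H * W, (R_xlen_t)cout * 8);
  const double *yp = dy.begin();
  for (int c = 0; c < cout; ++c) {
    const double *yc = yp + (R_xlen_t)c * Do * Ho * Wo;
    for (int ow = 0; ow < 2; ++ow)
      for (int oh = 0; oh < 2; ++oh)
        for (int od = 0; od < 2; ++od) {
          R_xlen_t col = (R_xlen_t)c * 8 + ow * 4 + oh * 2 + od;
          double *dst = &cols(0, col);
          R_xlen_t r = 0;
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              for (int d = 0; d < D; ++d) {
                dst[r++] = yc[(R_xlen_t)(2 * w + ow) * Ho * Do +
                              (R_xlen_t)(2 * h + oh) * Do + (2 * d + od)];
              }
        }
  }
  return cols;
}

// Fused batch-norm + ReLU applied in place on a (Nvox, C) matrix of
// conv outputs; returns xhat (normalized pre-scale values) alongside.
// [[Rcpp::export]]
List cpp_bn_relu(NumericMatrix z, NumericVector mu, NumericVector istd,
                 NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = z.nrow();
  const int C = z.ncol();
  NumericMatrix xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = istd[c], g = gamma[c], b = beta[c];
    const double *zc = &z(0, c);
    double *xc = &xhat(0, c);
    double *yc = &y(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      double xh = (zc[i] - m) * s;
      xc[i] = xh;
      double v = g * xh + b;
      yc[i] = v > 0 ? v : 0;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat);
}

// Per-channel sums and sums of squares of a (Nvox, C) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_col_moments(NumericMatrix z) {
  const R_xlen_t n = z.nrow();
  const int C = z.ncol();
  NumericMatrix out(2, C);
  for (int c = 0; c < C; ++c) {
    const double *zc = &z(0, c);
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      s += zc[i];
      s2 += zc[i] * zc[i];
    }
    out(0, c) = s;
    out(1, c) = s2;
  }
  return out;
}

// Fused BN backward: given upstream dY (already ReLU-masked), xhat and
// the per-channel reductions, form dZ in place:
// dZ = gamma*istd * (dY - mean_dy - xhat * mean_dyxh)
// [[Rcpp::export]]
NumericMatrix cpp_bn_backward(NumericMatrix dy, NumericMatrix xhat,
                              NumericVector gamma, NumericVector istd,
                              NumericVector mean_dy,
                              NumericVector mean_dyxh) {
  const R_xlen_t n = dy.nrow();
  const int C = dy.ncol();
  NumericMatrix dz(n, C);
  for (int c = 0; c < C; ++c) {
    const double gs = gamma[c] * istd[c];
    const double md = mean_dy[c], mx = mean_dyxh[c];
    const double *dyc = &dy(0, c);
    const double *xc = &xhat(0, c);
    double *dzc = &dz(0, c);
    for (R_xlen_t i = 0; i < n; ++i)
      dzc[i] = gs * (dyc[i] - md - xc[i] * mx);
  }
  return dz;
}

// ReLU mask + per-channel reductions for the BN backward: zeroes dy
// where gamma*xhat+beta <= 0 (in place on a copy) and returns the
// masked dy plus colSums(dy) and colSums(dy*xhat).
// [[Rcpp::export]]
List cpp_relu_mask_reduce(NumericMatrix dy, NumericMatrix xhat,
                          NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = dy.nrow();
  const int C = dy.ncol();
  NumericMatrix out(n, C);
  NumericVector sdy(C), sdyx(C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], b = beta[c];
    const double *dyc = &dy(0, c);
    const double *xc = &xhat(0, c);
    double *oc = &out(0, c);
    double s = 0, sx = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = (g * xc[i] + b > 0) ? dyc[i] : 0.0;
      oc[i] = v;
      s += v;
      sx += v * xc[i];
    }
    sdy[c] = s;
    sdyx[c] = sx;
  }
  return List::create(Named("dy") = out, Named("sum_dy") = sdy,
                      Named("sum_dyxh") = sdyx);
}
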