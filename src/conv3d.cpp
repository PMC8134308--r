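// Dense 3D layer primitives for the small U-Net segmenter.
//
// Array layout follows R column-major order with dims (D, H, W, C).
// Convolutions are 3x3x3, zero-padded ("same"); they are realized as
// im2col + BLAS matmul on the R side, so only the gather/scatter kernels
// live here. The im2col column index is kd + 3*kh + 9*kw + 27*c, matching a
// weight array of dims (3, 3, 3, C_in, C_out) flattened to (27*C_in, C_out).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cp_im2col(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int N = D * H * W;
  NumericMatrix out(N, 27 * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * N;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        for (int kd = 0; kd < 3; ++kd) {
          double* col = op + (size_t)(kd + 3 * kh + 9 * kw + 27 * c) * N;
          const int od = kd - 1, oh = kh - 1, ow = kw - 1;
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            const bool wok = sw >= 0 && sw < W;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              const bool hok = wok && sh >= 0 && sh < H;
              double* dst = col + (size_t)(h + H * w) * D;
              if (!hok) {
                for (int d = 0; d < D; ++d) dst[d] = 0.0;
                continue;
              }
              const double* src = xc + (size_t)(sh + H * sw) * D + od;
              const int d0 = (od < 0) ? 1 : 0;
              const int d1 = (od > 0) ? D - 1 : D;
              if (d0 > 0) dst[0] = 0.0;
              if (d1 < D) dst[D - 1] = 0.0;
              for (int d = d0; d < d1; ++d) dst[d] = src[d];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cp_col2im(NumericMatrix cols, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int N = D * H * W;
  NumericVector out((size_t)N * C);
  double* op = out.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = op + (size_t)c * N;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        for (int kd = 0; kd < 3; ++kd) {
          const double* col = cp + (size_t)(kd + 3 * kh + 9 * kw + 27 * c) * N;
          const int od = kd - 1, oh = kh - 1, ow = kw - 1;
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              double* dst = xc + (size_t)(sh + H * sw) * D + od;
              const double* src = col + (size_t)(h + H * w) * D;
              const int d0 = (od < 0) ? 1 : 0;
              const int d1 = (od > 0) ? D - 1 : D;
              for (int d = d0; d < d1; ++d) dst[d] += src[d];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

// 2x2x2 max pooling; returns pooled values and 1-based argmax linear indices
// [[Rcpp::export]]
List cp_maxpool_fw(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const size_t No = (size_t)Do * Ho * Wo * C;
  NumericVector y(No);
  IntegerVector idx(No);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)c * D * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d, ++o) {
          double best = -1e300; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                size_t i = coff + (size_t)(2 * d + dd) +
                           (size_t)D * ((2 * h + dh) + (size_t)H * (2 * w + dw));
                if (xp[i] > best) { best = xp[i]; bi = i; }
              }
          y[o] = best;
          idx[o] = (int)(bi + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cp_maxpool_bw(NumericVector dy, IntegerVector idx, IntegerVector dims) {
  NumericVector dx((size_t)dims[0] * dims[1] * dims[2] * dims[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = dims;
  return dx;
}

static inline void lin_coef(int o, int n_in, int& i0, int& i1, double& w1) {
  // output center (o + 0.5)/2 - 0.5 in input coordinates, clamped borders
  double p = (o + 0.5) / 2.0 - 0.5;
  if (p <= 0) { i0 = i1 = 0; w1 = 0.0; return; }
  if (p >= n_in - 1) { i0 = i1 = n_in - 1; w1 = 0.0; return; }
  i0 = (int)p; i1 = i0 + 1; w1 = p - i0;
}

// trilinear 2x upsampling
// [[Rcpp::export]]
NumericVector cp_upsample_fw(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Do * Ho * Wo * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<int> d0(Do), d1(Do), h0(Ho), h1(Ho), w0(Wo), w1i(Wo);
  std::vector<double> dwt(Do), hwt(Ho), wwt(Wo);
  for (int o = 0; o < Do; ++o) lin_coef(o, D, d0[o], d1[o], dwt[o]);
  for (int o = 0; o < Ho; ++o) lin_coef(o, H, h0[o], h1[o], hwt[o]);
  for (int o = 0; o < Wo; ++o) lin_coef(o, W, w0[o], w1i[o], wwt[o]);
  size_t oidx = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * D * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d, ++oidx) {
          double acc = 0.0;
          for (int bw = 0; bw < 2; ++bw) {
            const int iw = bw ? w1i[w] : w0[w];
            const double fw = bw ? wwt[w] : 1.0 - wwt[w];
            if (fw == 0.0) continue;
            for (int bh = 0; bh < 2; ++bh) {
              const int ih = bh ? h1[h] : h0[h];
              const double fh = bh ? hwt[h] : 1.0 - hwt[h];
              if (fh == 0.0) continue;
              for (int bd = 0; bd < 2; ++bd) {
                const int id = bd ? d1[d] : d0[d];
                const double fd = bd ? dwt[d] : 1.0 - dwt[d];
                if (fd == 0.0) continue;
                acc += fw * fh * fd * xc[(size_t)id + (size_t)D * (ih + (size_t)H * iw)];
              }
            }
          }
          yp[oidx] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return y;
}

// transpose of cp_upsample_fw
// [[Rcpp::export]]
NumericVector cp_upsample_bw(NumericVector dy, IntegerVector dims_in) {
  const int D = dims_in[0], H = dims_in[1], W = dims_in[2], C = dims_in[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)D * H * W * C);
  const double* gp = dy.begin();
  double* xp = dx.begin();
  std::vector<int> d0(Do), d1(Do), h0(Ho), h1(Ho), w0(Wo), w1i(Wo);
  std::vector<double> dwt(Do), hwt(Ho), wwt(Wo);
  for (int o = 0; o < Do; ++o) lin_coef(o, D, d0[o], d1[o], dwt[o]);
  for (int o = 0; o < Ho; ++o) lin_coef(o, H, h0[o], h1[o], hwt[o]);
  for (int o = 0; o < Wo; ++o) lin_coef(o, W, w0[o], w1i[o], wwt[o]);
  size_t oidx = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * D * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d, ++oidx) {
          const double g = gp[oidx];
          if (g == 0.0) continue;
          for (int bw = 0; bw < 2; ++bw) {
            const int iw = bw ? w1i[w] : w0[w];
            const double fw = bw ? wwt[w] : 1.0 - wwt[w];
            if (fw == 0.0) continue;
            for (int bh = 0; bh < 2; ++bh) {
              const int ih = bh ? h1[h] : h0[h];
              const double fh = bh ? hwt[h] : 1.0 - hwt[h];
              if (fh == 0.0) continue;
              for (int bd = 0; bd < 2; ++bd) {
                const int id = bd ? d1[d] : d0[d];
                const double fd = bd ? dwt[d] : 1.0 - dwt[d];
                if (fd == 0.0) continue;
                xc[(size_t)id + (size_t)D * (ih + (size_t)H * iw)] += fw * fh * fd * g;
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return dx;
}
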