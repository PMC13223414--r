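#include <Rcpp.h>
using namespace Rcpp;

// Dense 2-D image tensors are stored as native R arrays dim (H, W, C),
// column-major: index (i, j, c) -> i + H*j + H*W*c.
// im2col column index for kernel offset (ki, kj) and channel c:
// ki + kh*kj + kh*kw*c, so a (kh, kw, Cin, Cout) weight array reshaped
// column-major to a (kh*kw*Cin) x Cout matrix lines up exactly.

static inline int idx3(int i, int j, int c, int H, int W) {
  return i + H * j + H * W * c;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride,
                         int pad_top, int pad_left, int Ho, int Wo) {
  NumericMatrix out(Ho * Wo, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int col = ki + kh * kj + kh * kw * c;
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * stride - pad_left + kj;
          bool jin = (j >= 0 && j < W);
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * stride - pad_top + ki;
            double v = 0.0;
            if (jin && i >= 0 && i < H) v = x[idx3(i, j, c, H, W)];
            out(oi + Ho * oj, col) = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride,
                         int pad_top, int pad_left, int Ho, int Wo) {
  NumericVector out(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int col = ki + kh * kj + kh * kw * c;
        for (int oj = 0; oj < Wo; ++oj) {
          int j = oj * stride - pad_left + kj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int i = oi * stride - pad_top + ki;
            if (i < 0 || i >= H) continue;
            out[idx3(i, j, c, H, W)] += cols(oi + Ho * oj, col);
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Depthwise convolution: one k x k kernel per channel.
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             int H, int W, int C, int kh, int kw,
                             int stride, int pad_top, int pad_left,
                             int Ho, int Wo) {
  NumericVector out(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double acc = 0.0;
        for (int kj = 0; kj < kw; ++kj) {
          int j = oj * stride - pad_left + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int i = oi * stride - pad_top + ki;
            if (i < 0 || i >= H) continue;
            acc += x[idx3(i, j, c, H, W)] * w[ki + kh * kj + kh * kw * c];
          }
        }
        out[oi + Ho * oj + Ho * Wo * c] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int H, int W, int C, int kh, int kw,
                    int stride, int pad_top, int pad_left,
                    int Ho, int Wo) {
  NumericVector gx(H * W * C);
  NumericVector gw(kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double g = gout[oi + Ho * oj + Ho * Wo * c];
        if (g == 0.0) continue;
        for (int kj = 0; kj < kw; ++kj) {
          int j = oj * stride - pad_left + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int i = oi * stride - pad_top + ki;
            if (i < 0 || i >= H) continue;
            gx[idx3(i, j, c, H, W)] += g * w[ki + kh * kj + kh * kw * c];
            gw[ki + kh * kj + kh * kw * c] += g * x[idx3(i, j, c, H, W)];
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  gw.attr("dim") = IntegerVector::create(kh, kw, C);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// In-place AdamW update on one parameter tensor. The caller guarantees the
// buffers are privately owned (fresh optimizer state; parameter values are
// deep-copied on checkpoint load).
// [[Rcpp::export]]
void cpp_adamw_update(NumericVector p, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double wd, double b1,
                      double b2, double eps, double bc1, double bc2) {
  int n = p.size();
  for (int i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * ((m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps) + wd * p[i]);
  }
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Boundary-aligned bilinear gather: out(i,j,c) = B(i + O(i,j,2c), j + O(i,j,2c+1), c)
// for the 4 boundary channels c; sample coordinates clamped to the map border.
// [[Rcpp::export]]
NumericVector cpp_offset_sample_fwd(NumericVector B, NumericVector O,
                                    int H, int W) {
  NumericVector out(H * W * 4);
  for (int c = 0; c < 4; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double si = clampd(i + O[idx3(i, j, 2 * c, H, W)], 0.0, H - 1.0);
        double sj = clampd(j + O[idx3(i, j, 2 * c + 1, H, W)], 0.0, W - 1.0);
        int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        double fi = si - i0, fj = sj - j0;
        double v00 = B[idx3(i0, j0, c, H, W)], v10 = B[idx3(i1, j0, c, H, W)];
        double v01 = B[idx3(i0, j1, c, H, W)], v11 = B[idx3(i1, j1, c, H, W)];
        out[idx3(i, j, c, H, W)] =
          v00 * (1 - fi) * (1 - fj) + v10 * fi * (1 - fj) +
          v01 * (1 - fi) * fj + v11 * fi * fj;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, 4);
  return out;
}

// [[Rcpp::export]]
List cpp_offset_sample_bwd(NumericVector B, NumericVector O,
                           NumericVector gout, int H, int W) {
  NumericVector gB(H * W * 4);
  NumericVector gO(H * W * 8);
  for (int c = 0; c < 4; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double g = gout[idx3(i, j, c, H, W)];
        if (g == 0.0) continue;
        double ri = i + O[idx3(i, j, 2 * c, H, W)];
        double rj = j + O[idx3(i, j, 2 * c + 1, H, W)];
        bool ci = (ri <= 0.0 || ri >= H - 1.0);
        bool cj = (rj <= 0.0 || rj >= W - 1.0);
        double si = clampd(ri, 0.0, H - 1.0), sj = clampd(rj, 0.0, W - 1.0);
        int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        double fi = si - i0, fj = sj - j0;
        double v00 = B[idx3(i0, j0, c, H, W)], v10 = B[idx3(i1, j0, c, H, W)];
        double v01 = B[idx3(i0, j1, c, H, W)], v11 = B[idx3(i1, j1, c, H, W)];
        gB[idx3(i0, j0, c, H, W)] += g * (1 - fi) * (1 - fj);
        gB[idx3(i1, j0, c, H, W)] += g * fi * (1 - fj);
        gB[idx3(i0, j1, c, H, W)] += g * (1 - fi) * fj;
        gB[idx3(i1, j1, c, H, W)] += g * fi * fj;
        if (!ci)
          gO[idx3(i, j, 2 * c, H, W)] +=
            g * ((v10 - v00) * (1 - fj) + (v11 - v01) * fj);
        if (!cj)
          gO[idx3(i, j, 2 * c + 1, H, W)] +=
            g * ((v01 - v00) * (1 - fi) + (v11 - v10) * fi);
      }
    }
  }
  gB.attr("dim") = IntegerVector::create(H, W, 4);
  gO.attr("dim") = IntegerVector::create(H, W, 8);
  return List::create(_["gB"] = gB, _["gO"] = gO);
}
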