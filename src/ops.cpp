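#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Tensors are passed as flat numeric vectors in column-major (H, W, C, N)
// layout; kernels index them directly to avoid copies on the R side.

static inline size_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (size_t)h + (size_t)H * ((size_t)w + (size_t)W * ((size_t)c + (size_t)C * n));
}

// Unfold (im2col): rows ordered (kh fastest, then kw, then channel), columns
// ordered (out-row fastest, then out-col, then image). Out-of-bounds taps are
// zero (zero padding).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  const int OH = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  const int OW = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  if (OH < 1 || OW < 1) stop("kernel larger than padded input");
  NumericMatrix cols((R_xlen_t)kh * kw * C, (R_xlen_t)OH * OW * N);
  double* out = cols.begin();
  const double* in = x.begin();
  const size_t nrow = (size_t)kh * kw * C;
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const size_t col = (size_t)oh + (size_t)OH * ((size_t)ow + (size_t)OW * n);
        double* dst = out + col * nrow;
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < kw; ++j) {
            const int w0 = ow * sw - pw + j * dw;
            const bool win = (w0 >= 0 && w0 < W);
            for (int i = 0; i < kh; ++i) {
              const int h0 = oh * sh - ph + i * dh;
              double v = 0.0;
              if (win && h0 >= 0 && h0 < H)
                v = in[idx4(h0, w0, c, n, H, W, C)];
              dst[i + kh * (j + kw * c)] = v;
            }
          }
      }
  return cols;
}

// Fold (col2im): adjoint of im2col_cpp, accumulating overlapping taps.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  const int OH = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  const int OW = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* out = dx.begin();
  const double* in = cols.begin();
  const size_t nrow = (size_t)kh * kw * C;
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const size_t col = (size_t)oh + (size_t)OH * ((size_t)ow + (size_t)OW * n);
        const double* src = in + col * nrow;
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < kw; ++j) {
            const int w0 = ow * sw - pw + j * dw;
            if (w0 < 0 || w0 >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int h0 = oh * sh - ph + i * dh;
              if (h0 < 0 || h0 >= H) continue;
              out[idx4(h0, w0, c, n, H, W, C)] += src[i + kh * (j + kw * c)];
            }
          }
      }
  return dx;
}

struct BilinTap { int lo, hi; double t; };

static void bilin_taps(int in_size, int out_size, std::vector<BilinTap>& taps) {
  taps.resize(out_size);
  const double scale = (double)in_size / out_size;
  for (int o = 0; o < out_size; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in_size - 1) src = in_size - 1;
    int lo = (int)std::floor(src);
    int hi = lo + 1 < in_size ? lo + 1 : in_size - 1;
    taps[o].lo = lo;
    taps[o].hi = hi;
    taps[o].t = src - lo;
  }
}

// Bilinear resize (align_corners = FALSE convention).
// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                               int OH, int OW) {
  NumericVector y((R_xlen_t)OH * OW * C * N);
  std::vector<BilinTap> th, tw;
  bilin_taps(H, OH, th);
  bilin_taps(W, OW, tw);
  const double* in = x.begin();
  double* out = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow) {
        const BilinTap& bw = tw[ow];
        for (int oh = 0; oh < OH; ++oh) {
          const BilinTap& bh = th[oh];
          const double v =
            (1 - bh.t) * (1 - bw.t) * in[idx4(bh.lo, bw.lo, c, n, H, W, C)] +
            bh.t       * (1 - bw.t) * in[idx4(bh.hi, bw.lo, c, n, H, W, C)] +
            (1 - bh.t) * bw.t       * in[idx4(bh.lo, bw.hi, c, n, H, W, C)] +
            bh.t       * bw.t       * in[idx4(bh.hi, bw.hi, c, n, H, W, C)];
          out[idx4(oh, ow, c, n, OH, OW, C)] = v;
        }
      }
  return y;
}

// Adjoint of bilinear_fwd_cpp.
// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector g, int OH, int OW, int C, int N,
                               int H, int W) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  std::vector<BilinTap> th, tw;
  bilin_taps(H, OH, th);
  bilin_taps(W, OW, tw);
  const double* in = g.begin();
  double* out = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow) {
        const BilinTap& bw = tw[ow];
        for (int oh = 0; oh < OH; ++oh) {
          const BilinTap& bh = th[oh];
          const double gv = in[idx4(oh, ow, c, n, OH, OW, C)];
          out[idx4(bh.lo, bw.lo, c, n, H, W, C)] += (1 - bh.t) * (1 - bw.t) * gv;
          out[idx4(bh.hi, bw.lo, c, n, H, W, C)] += bh.t       * (1 - bw.t) * gv;
          out[idx4(bh.lo, bw.hi, c, n, H, W, C)] += (1 - bh.t) * bw.t       * gv;
          out[idx4(bh.hi, bw.hi, c, n, H, W, C)] += bh.t       * bw.t       * gv;
        }
      }
  return dx;
}

// Max pooling; returns pooled values plus the 0-based flat index of each
// winning input element so the backward pass can scatter gradients.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                     int k, int s, int p) {
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericVector y((R_xlen_t)OH * OW * C * N);
  IntegerVector arg((R_xlen_t)OH * OW * C * N);
  const double* in = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -DBL_MAX;
          size_t bi = 0;
          for (int j = 0; j < k; ++j) {
            const int w0 = ow * s - p + j;
            if (w0 < 0 || w0 >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int h0 = oh * s - p + i;
              if (h0 < 0 || h0 >= H) continue;
              const size_t ii = idx4(h0, w0, c, n, H, W, C);
              if (in[ii] > best) { best = in[ii]; bi = ii; }
            }
          }
          const size_t oi = idx4(oh, ow, c, n, OH, OW, C);
          y[oi] = best;
          arg[oi] = (int)bi;
        }
  return List::create(_["value"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector g, IntegerVector argmax,
                              R_xlen_t input_len) {
  NumericVector dx(input_len);
  for (R_xlen_t i = 0; i < g.size(); ++i) dx[argmax[i]] += g[i];
  return dx;
}

// ACE chromatic/spatial adjustment for one channel: for every pixel p sum
// r(I(p) - I(j)) / d(p, j) over the neighborhood (all pixels if radius <= 0,
// else a square window of the given radius), excluding j = p. r is the
// saturated slope function clip(x / T, -1, 1); d is Euclidean pixel distance.
// [[Rcpp::export]]
NumericMatrix ace_rc_cpp(NumericMatrix ch, double T, int radius) {
  const int H = ch.nrow(), W = ch.ncol();
  NumericMatrix rc(H, W);
  for (int pw = 0; pw < W; ++pw)
    for (int ph = 0; ph < H; ++ph) {
      const double ip = ch(ph, pw);
      double acc = 0.0;
      const int h0 = radius > 0 ? std::max(0, ph - radius) : 0;
      const int h1 = radius > 0 ? std::min(H - 1, ph + radius) : H - 1;
      const int w0 = radius > 0 ? std::max(0, pw - radius) : 0;
      const int w1 = radius > 0 ? std::min(W - 1, pw + radius) : W - 1;
      for (int jw = w0; jw <= w1; ++jw)
        for (int jh = h0; jh <= h1; ++jh) {
          if (jh == ph && jw == pw) continue;
          double r = (ip - ch(jh, jw)) / T;
          if (r > 1.0) r = 1.0;
          if (r < -1.0) r = -1.0;
          const double dh = ph - jh, dw = pw - jw;
          acc += r / std::sqrt(dh * dh + dw * dw);
        }
      rc(ph, pw) = acc;
    }
  return rc;
}
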