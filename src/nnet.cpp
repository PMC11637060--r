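// Convolutional network primitives: 2D convolution (im2col + GEMM) with
// stride and symmetric zero padding, 2x2 max pooling, and nearest/bilinear
// resizing, each with its adjoint for backpropagation. Feature maps are
// arma::cube (H, W, C), matching R arrays of dim c(H, W, C). Weights are
// (Cout x Cin*kh*kw) matrices with kernel elements ordered (kh, kw, Cin),
// i.e. column-major over an array of dim c(kh, kw, Cin, Cout).
//
// The patch matrix uses layout (Ho*Wo x kh*kw*Cin) so that the innermost
// loops walk down contiguous columns.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// patch matrix: (Ho*Wo) x (kh*kw*C); column r = c*kh*kw + dw*kh + dh holds
// x(ho*sh - ph + dh, wo*sw - pw + dw, c) at row wo*Ho + ho.
static mat im2col(const cube& x, int kh, int kw, int sh, int sw,
                  int ph, int pw, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(Ho * Wo, (size_t)kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = c * kh * kw + dw * kh + dh;
        double* dst = col.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          const double* src = xs.colptr(wi);
          double* d = dst + (size_t)wo * Ho;
          const int h0 = -ph + dh;
          int ho = (h0 < 0) ? ((-h0 + sh - 1) / sh) : 0;
          int hi = h0 + ho * sh;
          for (; ho < Ho && hi < H; ++ho, hi += sh) d[ho] = src[hi];
        }
      }
    }
  }
  return col;
}

static void col2im_add(cube& gx, const mat& col, int kh, int kw, int sh,
                       int sw, int ph, int pw, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    mat& xs = gx.slice(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = c * kh * kw + dw * kh + dh;
        const double* src0 = col.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          double* dst = xs.colptr(wi);
          const double* s = src0 + (size_t)wo * Ho;
          const int h0 = -ph + dh;
          int ho = (h0 < 0) ? ((-h0 + sh - 1) / sh) : 0;
          int hi = h0 + ho * sh;
          for (; ho < Ho && hi < H; ++ho, hi += sh) dst[hi] += s[ho];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw, int sh, int sw,
                          int ph, int pw) {
  const int Ho = out_dim(x.n_rows, kh, sh, ph);
  const int Wo = out_dim(x.n_cols, kw, sw, pw);
  const int Cout = w.n_rows;
  mat col = im2col(x, kh, kw, sh, sw, ph, pw, Ho, Wo);
  mat y = col * w.t();           // (Ho*Wo x Cout)
  y.each_row() += b.t();
  return cube(y.memptr(), Ho, Wo, Cout);
}

// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& w,
                           const arma::cube& gy, int kh, int kw, int sh,
                           int sw, int ph, int pw) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  const mat gym((double*)gy.memptr(), (size_t)Ho * Wo, Cout);
  mat col = im2col(x, kh, kw, sh, sw, ph, pw, Ho, Wo);
  mat gw = gym.t() * col;        // (Cout x K)
  vec gb = sum(gym, 0).t();
  mat gcol = gym * w;            // (Ho*Wo x K)
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_add(gx, gcol, kh, kw, sh, sw, ph, pw, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C); // 0..3: (dh, dw) = (idx %% 2, idx / 2)
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -datum::inf;
        int bi = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            double v = x(2 * ho + dh, 2 * wo + dw, c);
            if (v > best) { best = v; bi = dw * 2 + dh; }
          }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::cube& gy, const arma::ucube& idx,
                             int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int bi = (int)idx(ho, wo, c);
        gx(2 * ho + bi % 2, 2 * wo + bi / 2, c) += gy(ho, wo, c);
      }
  return gx;
}

// Bilinear resize with the pixel-centre (align_corners = FALSE) convention.
static void bilinear_weights(int n_in, int n_out, ivec& i0, ivec& i1,
                             vec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
  const double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    int lo = (int)std::floor(src);
    double frac = src - lo;
    int hi = lo + 1;
    if (lo < 0) { lo = 0; hi = 0; frac = 0.0; }
    if (hi >= n_in) { hi = n_in - 1; lo = n_in - 1; frac = 0.0; }
    i0(o) = lo; i1(o) = hi; w1(o) = frac;
  }
}

// [[Rcpp::export(name = ".resize_bilinear_forward")]]
arma::cube resize_bilinear_forward(const arma::cube& x, int Ho, int Wo) {
  ivec r0, r1, c0, c1; vec rw, cw;
  bilinear_weights(x.n_rows, Ho, r0, r1, rw);
  bilinear_weights(x.n_cols, Wo, c0, c1, cw);
  cube y(Ho, Wo, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) {
    const mat& xs = x.slice(c);
    mat& ys = y.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      const double* xl = xs.colptr(c0(wo));
      const double* xr = xs.colptr(c1(wo));
      double* yc = ys.colptr(wo);
      const double wcf = cw(wo);
      for (int ho = 0; ho < Ho; ++ho) {
        double a = xl[r0(ho)] * (1 - rw(ho)) + xl[r1(ho)] * rw(ho);
        double b = xr[r0(ho)] * (1 - rw(ho)) + xr[r1(ho)] * rw(ho);
        yc[ho] = a * (1 - wcf) + b * wcf;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".resize_bilinear_backward")]]
arma::cube resize_bilinear_backward(const arma::cube& gy, int H, int W) {
  ivec r0, r1, c0, c1; vec rw, cw;
  bilinear_weights(H, gy.n_rows, r0, r1, rw);
  bilinear_weights(W, gy.n_cols, c0, c1, cw);
  cube gx(H, W, gy.n_slices, fill::zeros);
  for (uword c = 0; c < gy.n_slices; ++c) {
    mat& gs = gx.slice(c);
    const mat& gys = gy.slice(c);
    for (uword wo = 0; wo < gy.n_cols; ++wo) {
      double* gl = gs.colptr(c0(wo));
      double* gr = gs.colptr(c1(wo));
      const double* g0 = gys.colptr(wo);
      const double wcf = cw(wo);
      for (uword ho = 0; ho < gy.n_rows; ++ho) {
        const double g = g0[ho];
        gl[r0(ho)] += g * (1 - rw(ho)) * (1 - wcf);
        gl[r1(ho)] += g * rw(ho) * (1 - wcf);
        gr[r0(ho)] += g * (1 - rw(ho)) * wcf;
        gr[r1(ho)] += g * rw(ho) * wcf;
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample2_forward")]]
arma::cube upsample2_forward(const arma::cube& x) {
  cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword w = 0; w < x.n_cols; ++w) {
      const double* xc = x.slice(c).colptr(w);
      double* y0 = y.slice(c).colptr(2 * w);
      double* y1 = y.slice(c).colptr(2 * w + 1);
      for (uword h = 0; h < x.n_rows; ++h) {
        y0[2 * h] = y0[2 * h + 1] = xc[h];
        y1[2 * h] = y1[2 * h + 1] = xc[h];
      }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::cube upsample2_backward(const arma::cube& gy) {
  cube gx(gy.n_rows / 2, gy.n_cols / 2, gy.n_slices);
  for (uword c = 0; c < gy.n_slices; ++c)
    for (uword w = 0; w < gx.n_cols; ++w) {
      const double* g0 = gy.slice(c).colptr(2 * w);
      const double* g1 = gy.slice(c).colptr(2 * w + 1);
      double* gc = gx.slice(c).colptr(w);
      for (uword h = 0; h < gx.n_rows; ++h)
        gc[h] = g0[2 * h] + g0[2 * h + 1] + g1[2 * h] + g1[2 * h + 1];
    }
  return gx;
}
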