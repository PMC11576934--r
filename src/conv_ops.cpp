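// Hot loops of the 2D F-CNN: same-padding convolution (im2col + GEMM) and
// 2x2 max-pooling with index bookkeeping for decoder unpooling.
//
// Array layout throughout: column-major R arrays with dims
//   feature maps  (H, W, C, N)
//   conv weights  (kh, kw, Cin, Cout)
// so a (kh*kw*Cin) x Cout matrix view of the weight array needs no copy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector mk4(int a, int b, int c, int n) {
  NumericVector v((size_t)a * b * c * n);
  v.attr("dim") = IntegerVector::create(a, b, c, n);
  return v;
}

static inline IntegerVector mk4i(int a, int b, int c, int n) {
  IntegerVector v((size_t)a * b * c * n);
  v.attr("dim") = IntegerVector::create(a, b, c, n);
  return v;
}

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4D array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill the im2col matrix (kh*kw*Cin x H*W) for sample n with zero padding.
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, arma::mat &col) {
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double *dst = col.memptr() + (size_t)r; // stride = nrow
        const size_t nr = col.n_rows;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pw;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) dst[(size_t)(h + H * w) * nr] = 0.0;
            continue;
          }
          const double *src = xc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - ph;
            dst[(size_t)(h + H * w) * nr] =
                (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the padded input grid.
static void col2im_add(const arma::mat &col, int H, int W, int C,
                       int kh, int kw, double *gx) {
  const int ph = kh / 2, pw = kw / 2;
  const size_t nr = col.n_rows;
  for (int c = 0; c < C; ++c) {
    double *gc = gx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double *src = col.memptr() + (size_t)r;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pw;
          if (sw < 0 || sw >= W) continue;
          double *gcol = gc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - ph;
            if (sh < 0 || sh >= H) continue;
            gcol[sh] += src[(size_t)(h + H * w) * nr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("channel mismatch between input and kernel");
  if (b.size() != Cout) stop("bias length mismatch");

  NumericVector y = mk4(H, W, Cout, N);
  arma::mat wm(const_cast<double *>(w.begin()), (size_t)kh * kw * C, Cout,
               false, true);
  arma::mat col((size_t)kh * kw * C, (size_t)H * W);
  arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    arma::mat ym(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    ym = col.t() * wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx); get_dims4(w, dw); get_dims4(gy, dg);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];

  NumericVector gx = mk4(H, W, C, N);
  NumericVector gw = mk4(kh, kw, C, Cout);
  NumericVector gb(Cout);

  arma::mat wm(const_cast<double *>(w.begin()), (size_t)kh * kw * C, Cout,
               false, true);
  arma::mat gwm(gw.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);
  arma::mat col((size_t)kh * kw * C, (size_t)H * W);

  for (int n = 0; n < N; ++n) {
    arma::mat gym(const_cast<double *>(gy.begin()) + (size_t)n * H * W * Cout,
                  (size_t)H * W, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    gwm += col * gym;
    gbv += arma::sum(gym, 0);
    arma::mat gcol = wm * gym.t(); // (khkwC x HW)
    col2im_add(gcol, H, W, C, kh, kw, gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// 2x2 stride-2 max pooling (floor mode). Returns pooled values and, for each
// pooled element, the 1-based linear offset of the argmax inside its (H,W)
// slab, so the decoder can unpool onto the exact winning positions.
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x) {
  int dx[4];
  get_dims4(x, dx);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small to pool");

  NumericVector y = mk4(Ho, Wo, C, N);
  IntegerVector idx = mk4i(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xs = x.begin() + ((size_t)n * C + c) * H * W;
      double *ys = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      int *is = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          int best = 2 * h + H * (2 * w);
          double bv = xs[best];
          const int cand[3] = {2 * h + 1 + H * (2 * w),
                               2 * h + H * (2 * w + 1),
                               2 * h + 1 + H * (2 * w + 1)};
          for (int k = 0; k < 3; ++k) {
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
          }
          ys[h + Ho * w] = bv;
          is[h + Ho * w] = best + 1; // 1-based within the (H,W) slab
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// Scatter pooled gradients (or decoder features, for unpooling) back onto the
// (H, W) grid at the recorded argmax positions; all other entries are zero.
// [[Rcpp::export(name = ".maxpool_scatter")]]
NumericVector maxpool_scatter(NumericVector v, IntegerVector idx,
                              int H, int W) {
  int dv[4];
  get_dims4(v, dv);
  const int Ho = dv[0], Wo = dv[1], C = dv[2], N = dv[3];
  NumericVector out = mk4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *vs = v.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int *is = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      double *os = out.begin() + ((size_t)n * C + c) * H * W;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k) os[is[k] - 1] += vs[k];
    }
  }
  return out;
}

// Gather from the (H, W) grid at the recorded argmax positions: the backward
// pass of unpooling.
// [[Rcpp::export(name = ".maxpool_gather")]]
NumericVector maxpool_gather(NumericVector g, IntegerVector idx,
                             int Ho, int Wo) {
  int dg[4];
  get_dims4(g, dg);
  const int H = dg[0], W = dg[1], C = dg[2], N = dg[3];
  NumericVector out = mk4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *gs = g.begin() + ((size_t)n * C + c) * H * W;
      const int *is = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      double *os = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k) os[k] = gs[is[k] - 1];
    }
  }
  return out;
}
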