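// Minimal convolution kernels backing the network module: im2col-based
// 2-D convolution forward/backward (zero padding, arbitrary stride) and
// nearest-neighbour 2x up-sampling. Tensors are R arrays with dims
// (H, W, C, N) in column-major order; weights have dims (kh, kw, Cin, Cout)
// so that their memory layout is directly the (kh*kw*Cin) x Cout matrix.
#ifdef __GNUC__
#pragma GCC optimize("O3")
#endif
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

static void im2col(const double *x, int H, int W, int C, int kh, int kw,
                   int stride, int pad, int Ho, int Wo, arma::mat &cols) {
  // cols is (kh*kw*C) x (Ho*Wo)
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int m = oh + Ho * ow;
      double *dst = cols.colptr(m);
      for (int c = 0; c < C; ++c) {
        for (int q = 0; q < kw; ++q) {
          const int iw = ow * stride - pad + q;
          for (int p = 0; p < kh; ++p) {
            const int ih = oh * stride - pad + p;
            const int kidx = p + kh * (q + kw * c);
            dst[kidx] = (ih >= 0 && ih < H && iw >= 0 && iw < W)
                            ? x[ih + H * (iw + W * c)]
                            : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat &cols, int H, int W, int C, int kh,
                       int kw, int stride, int pad, int Ho, int Wo,
                       double *gx) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int m = oh + Ho * ow;
      const double *src = cols.colptr(m);
      for (int c = 0; c < C; ++c) {
        for (int q = 0; q < kw; ++q) {
          const int iw = ow * stride - pad + q;
          if (iw < 0 || iw >= W) continue;
          for (int p = 0; p < kh; ++p) {
            const int ih = oh * stride - pad + p;
            if (ih < 0 || ih >= H) continue;
            gx[ih + H * (iw + W * c)] += src[p + kh * (q + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int dx[4], dw[4];
  get_dims4(x, dx);
  get_dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int K = kh * kw * C;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int M = Ho * Wo;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wmat(const_cast<double *>(w.begin()), K, Cout, false, true);
  const arma::rowvec bias(const_cast<double *>(b.begin()), Cout, false, true);
  arma::mat cols(K, M);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat ym(y.begin() + (size_t)n * M * Cout, M, Cout, false, true);
    ym = cols.t() * Wmat;
    ym.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx);
  get_dims4(w, dw);
  get_dims4(gy, dg);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int Ho = dg[0], Wo = dg[1];
  const int K = kh * kw * C;
  const int M = Ho * Wo;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  const arma::mat Wmat(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat gWmat(gw.begin(), K, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);
  arma::mat cols(K, M);
  for (int n = 0; n < N; ++n) {
    const arma::mat Gy(const_cast<double *>(gy.begin()) + (size_t)n * M * Cout,
                       M, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    gWmat += cols * Gy;
    gbv += arma::sum(Gy, 0);
    arma::mat gcols = Wmat * Gy.t();  // K x M
    col2im_add(gcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
               gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *ys = y.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xs[h + H * w];
          ys[2 * h + H2 * (2 * w)] = v;
          ys[2 * h + 1 + H2 * (2 * w)] = v;
          ys[2 * h + H2 * (2 * w + 1)] = v;
          ys[2 * h + 1 + H2 * (2 * w + 1)] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  int d[4];
  get_dims4(gy, d);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gs = gy.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      double *xs = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          xs[h + H * w] = gs[2 * h + H2 * (2 * w)] +
                          gs[2 * h + 1 + H2 * (2 * w)] +
                          gs[2 * h + H2 * (2 * w + 1)] +
                          gs[2 * h + 1 + H2 * (2 * w + 1)];
    }
  return gx;
}
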