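// Minimal convolutional primitives for the compact style-conditioned
// generator and the small image regressors/embedders.  Layout convention:
// activations are H x W x C x N arrays (column-major, as R builds them),
// kernels are k x k x Cin x Cout with odd k and "same" zero padding,
// stride 1.  Convolutions are computed per sample as an im2col gather
// followed by one BLAS matrix product, which is what keeps CPU training
// of the GAN practical.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dv = x.attr("dim");
  if (dv.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dv[i];
}

// gather one sample into the im2col matrix: (H*W) x (k*k*C)
static void im2col(const double *x, int H, int W, int C, int k,
                   arma::mat &col) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        double *dst = col.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pad;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) dst[h + H * w] = 0.0;
            continue;
          }
          const double *src = xc + (size_t)H * sw;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - pad;
            dst[h + H * w] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// scatter-add the im2col gradient back onto the input gradient
static void col2im(const arma::mat &col, int H, int W, int C, int k,
                   double *dx) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double *dc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        const double *src = col.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pad;
          if (sw < 0 || sw >= W) continue;
          double *dst = dc + (size_t)H * sw;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - pad;
            if (sh >= 0 && sh < H) dst[sh] += src[h + H * w];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".nn_conv_fwd", rng = false)]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector K, NumericVector b) {
  int dx[4], dk[4];
  dims4(x, dx); dims4(K, dk);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dk[0], Cout = dk[3];
  if (dk[1] != k || dk[2] != C) stop("kernel dims do not match input channels");
  if (b.size() != Cout) stop("bias length mismatch");
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(K.begin(), (size_t)k * k * C, Cout, false, true);
  arma::mat col(H * W, (size_t)k * k * C);
  arma::rowvec bv(b.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, col);
    arma::mat ym(y.begin() + (size_t)H * W * Cout * n, H * W, Cout,
                 false, true);
    ym = col * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".nn_conv_bwd", rng = false)]]
List nn_conv_bwd(NumericVector x, NumericVector K, NumericVector dy) {
  int dxd[4], dk[4], dyd[4];
  dims4(x, dxd); dims4(K, dk); dims4(dy, dyd);
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int k = dk[0], Cout = dk[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dK((size_t)k * k * C * Cout);
  dK.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(K.begin(), (size_t)k * k * C, Cout, false, true);
  arma::mat dKm(dK.begin(), (size_t)k * k * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(H * W, (size_t)k * k * C);
  arma::mat dcol(H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(dy.begin() + (size_t)H * W * Cout * n, H * W, Cout,
                  false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, col);
    dKm += col.t() * dym;
    dbv += arma::sum(dym, 0).t();
    dcol = dym * Wm.t();
    col2im(dcol, H, W, C, k, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dK"] = dK, _["db"] = db);
}

// nearest-neighbour x2 upsampling
// [[Rcpp::export(name = ".nn_up2", rng = false)]]
NumericVector nn_up2(NumericVector x) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (int p = 0; p < C * N; ++p) {
    const double *xp = x.begin() + (size_t)H * W * p;
    double *yp = y.begin() + (size_t)H2 * W2 * p;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = xp[h + H * w];
        double *base = yp + 2 * h + H2 * 2 * w;
        base[0] = v; base[1] = v; base[H2] = v; base[H2 + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_up2_bwd", rng = false)]]
NumericVector nn_up2_bwd(NumericVector dy) {
  int d[4]; dims4(dy, d);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int p = 0; p < C * N; ++p) {
    const double *gp = dy.begin() + (size_t)H2 * W2 * p;
    double *xp = dx.begin() + (size_t)H * W * p;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double *base = gp + 2 * h + H2 * 2 * w;
        xp[h + H * w] = base[0] + base[1] + base[H2] + base[H2 + 1];
      }
  }
  return dx;
}

// 2x2 average pooling
// [[Rcpp::export(name = ".nn_pool2", rng = false)]]
NumericVector nn_pool2(NumericVector x) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (int p = 0; p < C * N; ++p) {
    const double *xp = x.begin() + (size_t)H * W * p;
    double *yp = y.begin() + (size_t)H2 * W2 * p;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const double *base = xp + 2 * h + H * 2 * w;
        yp[h + H2 * w] = 0.25 * (base[0] + base[1] + base[H] + base[H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_pool2_bwd", rng = false)]]
NumericVector nn_pool2_bwd(NumericVector dy) {
  int d[4]; dims4(dy, d);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = 2 * H2, W = 2 * W2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int p = 0; p < C * N; ++p) {
    const double *gp = dy.begin() + (size_t)H2 * W2 * p;
    double *xp = dx.begin() + (size_t)H * W * p;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const double g = 0.25 * gp[h + H2 * w];
        double *base = xp + 2 * h + H * 2 * w;
        base[0] = g; base[1] = g; base[H] = g; base[H + 1] = g;
      }
  }
  return dx;
}

// multiply each H x W plane (c, n) by the per-sample per-channel scale
// s[n, c] (s is an N x C matrix)
// [[Rcpp::export(name = ".nn_scale", rng = false)]]
NumericVector nn_scale(NumericVector x, NumericMatrix s) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = s(n, c);
      const double *xp = x.begin() + plane * (c + (size_t)C * n);
      double *yp = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yp[i] = sc * xp[i];
    }
  return y;
}

// per-(sample, channel) inner products sum_{h,w} a * b -> N x C matrix
// [[Rcpp::export(name = ".nn_plane_dot", rng = false)]]
NumericMatrix nn_plane_dot(NumericVector a, NumericVector b) {
  int d[4]; dims4(a, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericMatrix out(N, C);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *ap = a.begin() + plane * (c + (size_t)C * n);
      const double *bp = b.begin() + plane * (c + (size_t)C * n);
      double acc = 0.0;
      for (size_t i = 0; i < plane; ++i) acc += ap[i] * bp[i];
      out(n, c) = acc;
    }
  return out;
}
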