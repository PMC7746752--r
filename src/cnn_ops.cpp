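// Batched 2D convolution and max-pooling primitives for the slice
// classifier. A batch of B images with C channels of size H x W is stored
// as an R array of dim (H, W, C*B), image b occupying planes
// [b*C, b*C + C). Convolutions are 3x3, stride 1, zero padding 1 ("same"),
// realised as im2col + GEMM. All layouts are column-major (R convention).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3(const double* x, int H, int W, int C, arma::mat& col) {
  // col is (C*9) x (H*W); row r = c*9 + (dj+1)*3 + (di+1)
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)H * W * c;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int r = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) {
            for (int i = 0; i < H; ++i)
              col((arma::uword)r, (arma::uword)(i + (size_t)H * j)) = 0.0;
            continue;
          }
          const double* src = plane + (size_t)H * js;
          for (int i = 0; i < H; ++i) {
            int is = i + di;
            col((arma::uword)r, (arma::uword)(i + (size_t)H * j)) =
              (is < 0 || is >= H) ? 0.0 : src[is];
          }
        }
      }
  }
}

// [[Rcpp::export(name = ".convFwdC")]]
NumericVector convFwdC(NumericVector x, NumericMatrix Wm, NumericVector bias,
                       int C) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1];
  int B = d[2] / C;
  int K = Wm.nrow();
  arma::mat Wa(Wm.begin(), K, Wm.ncol(), false);
  NumericVector out((size_t)H * W * K * B);
  arma::mat col(C * 9, (size_t)H * W);
  for (int b = 0; b < B; ++b) {
    im2col3(x.begin() + (size_t)H * W * C * b, H, W, C, col);
    arma::mat Y = Wa * col;  // K x (H*W)
    Y.each_col() += arma::vec(bias.begin(), K);
    double* o = out.begin() + (size_t)H * W * K * b;
    for (int k = 0; k < K; ++k)
      for (size_t p = 0; p < (size_t)H * W; ++p)
        o[(size_t)H * W * k + p] = Y((arma::uword)k, (arma::uword)p);
  }
  out.attr("dim") = IntegerVector::create(H, W, K * B);
  return out;
}

// [[Rcpp::export(name = ".convBwdC")]]
List convBwdC(NumericVector x, NumericMatrix Wm, NumericVector dy, int C) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1];
  int B = d[2] / C;
  int K = Wm.nrow();
  arma::mat Wa(Wm.begin(), K, Wm.ncol(), false);
  arma::mat dW(K, C * 9, arma::fill::zeros);
  arma::vec db(K, arma::fill::zeros);
  NumericVector dx(x.size());
  arma::mat col(C * 9, (size_t)H * W);
  arma::mat dY(K, (size_t)H * W);
  for (int b = 0; b < B; ++b) {
    const double* dyp = dy.begin() + (size_t)H * W * K * b;
    for (int k = 0; k < K; ++k)
      for (size_t p = 0; p < (size_t)H * W; ++p)
        dY((arma::uword)k, (arma::uword)p) = dyp[(size_t)H * W * k + p];
    im2col3(x.begin() + (size_t)H * W * C * b, H, W, C, col);
    dW += dY * col.t();
    db += arma::sum(dY, 1);
    arma::mat dcol = Wa.t() * dY;  // (C*9) x (H*W)
    double* dxp = dx.begin() + (size_t)H * W * C * b;
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + (size_t)H * W * c;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int r = c * 9 + (dj + 1) * 3 + (di + 1);
          for (int j = 0; j < W; ++j) {
            int js = j + dj;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              int is = i + di;
              if (is < 0 || is >= H) continue;
              plane[is + (size_t)H * js] +=
                dcol((arma::uword)r, (arma::uword)(i + (size_t)H * j));
            }
          }
        }
    }
  }
  dx.attr("dim") = d;
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}

// 2x2 max pooling, stride 2; idx stores the winning quadrant (0..3).
// [[Rcpp::export(name = ".maxPoolFwdC")]]
List maxPoolFwdC(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], S = d[2];
  int oh = H / 2, ow = W / 2;
  NumericVector y((size_t)oh * ow * S);
  IntegerVector idx((size_t)oh * ow * S);
  const double* xp = x.begin();
  for (int s = 0; s < S; ++s) {
    const double* plane = xp + (size_t)H * W * s;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -1e300;
        int bq = 0;
        for (int q = 0; q < 4; ++q) {
          int di = q & 1, dj = q >> 1;
          double v = plane[(2 * i + di) + (size_t)H * (2 * j + dj)];
          if (v > best) { best = v; bq = q; }
        }
        size_t o = (size_t)oh * ow * s + i + (size_t)oh * j;
        y[o] = best;
        idx[o] = bq;
      }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, S);
  idx.attr("dim") = IntegerVector::create(oh, ow, S);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPoolBwdC")]]
NumericVector maxPoolBwdC(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector d = dy.attr("dim");
  int oh = d[0], ow = d[1], S = d[2];
  NumericVector dx((size_t)H * W * S);
  for (int s = 0; s < S; ++s) {
    double* plane = dx.begin() + (size_t)H * W * s;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        size_t o = (size_t)oh * ow * s + i + (size_t)oh * j;
        int q = idx[o];
        plane[(2 * i + (q & 1)) + (size_t)H * (2 * j + (q >> 1))] += dy[o];
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, S);
  return dx;
}
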