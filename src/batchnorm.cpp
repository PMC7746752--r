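// Per-channel batch normalisation over (H, W, K*B) activation arrays
// (channel k occupies planes k, k+K, ...). Training mode uses batch
// statistics and updates the running ones; inference applies the running
// statistics. ReLU is fused into the forward output; the backward kernel
// applies the corresponding mask before the batch-norm gradient.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;

// [[Rcpp::export(name = ".bnReluFwdC")]]
List bnReluFwdC(NumericVector a, int K, NumericVector gamma,
                NumericVector beta, NumericVector rm, NumericVector rv,
                bool training) {
  IntegerVector d = a.attr("dim");
  size_t plane = (size_t)d[0] * d[1];
  int S = d[2];
  int B = S / K;
  NumericVector out(a.size()), pre(a.size()), xhat(a.size());
  NumericVector sdv(K), rmOut = clone(rm), rvOut = clone(rv);
  const double* ap = a.begin();
  for (int k = 0; k < K; ++k) {
    double mu, va;
    size_t n = plane * B;
    if (training) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const double* p = ap + plane * ((size_t)b * K + k);
        for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu = s / n;
      va = s2 / n - mu * mu;
      if (va < 0) va = 0;
      rmOut[k] = (1 - BN_MOM) * rm[k] + BN_MOM * mu;
      rvOut[k] = (1 - BN_MOM) * rv[k] + BN_MOM * va;
    } else {
      mu = rm[k];
      va = rv[k];
    }
    double sd = std::sqrt(va + BN_EPS);
    sdv[k] = sd;
    double g = gamma[k], be = beta[k];
    for (int b = 0; b < B; ++b) {
      size_t off = plane * ((size_t)b * K + k);
      const double* p = ap + off;
      double* xo = xhat.begin() + off;
      double* po = pre.begin() + off;
      double* oo = out.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        double xh = (p[i] - mu) / sd;
        xo[i] = xh;
        double y = g * xh + be;
        po[i] = y;
        oo[i] = y > 0 ? y : 0.0;
      }
    }
  }
  out.attr("dim") = d;
  pre.attr("dim") = d;
  xhat.attr("dim") = d;
  return List::create(_["out"] = out, _["pre"] = pre, _["xhat"] = xhat,
                      _["sd"] = sdv, _["rm"] = rmOut, _["rv"] = rvOut);
}

// [[Rcpp::export(name = ".bnReluBwdC")]]
List bnReluBwdC(NumericVector dy, NumericVector pre, NumericVector xhat,
                NumericVector sdv, NumericVector gamma, int K) {
  IntegerVector d = dy.attr("dim");
  size_t plane = (size_t)d[0] * d[1];
  int S = d[2];
  int B = S / K;
  NumericVector dx(dy.size()), dG(K), dB(K);
  for (int k = 0; k < K; ++k) {
    size_t n = plane * B;
    double sum_d = 0, sum_dx = 0, sg = 0, sb = 0;
    // first pass: relu-masked dy statistics
    for (int b = 0; b < B; ++b) {
      size_t off = plane * ((size_t)b * K + k);
      const double* dp = dy.begin() + off;
      const double* pp = pre.begin() + off;
      const double* xp = xhat.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        double dv = pp[i] > 0 ? dp[i] : 0.0;
        sg += dv * xp[i];
        sb += dv;
        double dxh = dv * gamma[k];
        sum_d += dxh;
        sum_dx += dxh * xp[i];
      }
    }
    dG[k] = sg;
    dB[k] = sb;
    double md = sum_d / n, mdx = sum_dx / n, sd = sdv[k];
    for (int b = 0; b < B; ++b) {
      size_t off = plane * ((size_t)b * K + k);
      const double* dp = dy.begin() + off;
      const double* pp = pre.begin() + off;
      const double* xp = xhat.begin() + off;
      double* ox = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        double dxh = (pp[i] > 0 ? dp[i] : 0.0) * gamma[k];
        ox[i] = (dxh - md - xp[i] * mdx) / sd;
      }
    }
  }
  dx.attr("dim") = d;
  return List::create(_["dx"] = dx, _["dG"] = dG, _["dB"] = dB);
}
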