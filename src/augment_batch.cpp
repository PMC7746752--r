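// Batched slice augmentation: for each slice, one bilinear similarity
// warp (rotation, scale, translation), contrast and gamma intensity maps
// with clipping, centre crop, bilinear resize to the backbone input size,
// and replication to three identical channels.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double bilin2(const double* v, int nx, int ny, double x,
                            double y) {
  if (x < -1.0 || y < -1.0 || x > nx || y > ny) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double acc = 0.0;
  for (int dy = 0; dy < 2; ++dy) {
    int yi = y0 + dy;
    if (yi < 0 || yi >= ny) continue;
    double wy = dy ? fy : 1.0 - fy;
    for (int dx = 0; dx < 2; ++dx) {
      int xi = x0 + dx;
      if (xi < 0 || xi >= nx) continue;
      acc += (dx ? fx : 1.0 - fx) * wy * v[xi + (size_t)nx * yi];
    }
  }
  return acc;
}

// native: (H, W, B); params: 6 x B rows (rotDeg, scale, tx, ty, contrast,
// gamma); returns (outSize, outSize, 3*B).
// [[Rcpp::export(name = ".augmentBatchC")]]
NumericVector augmentBatchC(NumericVector native, NumericMatrix params,
                            int cropSize, int outSize) {
  IntegerVector d = native.attr("dim");
  int H = d[0], W = d[1], B = d[2];
  int cs = cropSize > 0 ? std::min(cropSize, std::min(H, W)) : std::min(H, W);
  int o1 = (H - cs) / 2, o2 = (W - cs) / 2;
  NumericVector out((size_t)outSize * outSize * 3 * B);
  std::vector<double> warped((size_t)H * W);
  double cxp = (H - 1) / 2.0, cyp = (W - 1) / 2.0;
  for (int b = 0; b < B; ++b) {
    const double* img = native.begin() + (size_t)H * W * b;
    double th = params(0, b) * M_PI / 180.0;
    double sc = params(1, b), tx = params(2, b), ty = params(3, b);
    double ct = params(4, b), gm = params(5, b);
    double c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double ux = (i - cxp - tx) / sc, uy = (j - cyp - ty) / sc;
        double v = bilin2(img, H, W, c * ux + s * uy + cxp,
                          -s * ux + c * uy + cyp);
        v = ct * (v - 0.5) + 0.5;
        if (v < 0) v = 0; else if (v > 1) v = 1;
        v = std::pow(v, gm);
        if (v < 0) v = 0; else if (v > 1) v = 1;
        warped[i + (size_t)H * j] = v;
      }
    double* ob = out.begin() + (size_t)outSize * outSize * 3 * b;
    double sx = (double)cs / outSize, sy = (double)cs / outSize;
    for (int j = 0; j < outSize; ++j) {
      double y = (j + 0.5) * sy - 0.5 + o2;
      for (int i = 0; i < outSize; ++i) {
        double x = (i + 0.5) * sx - 0.5 + o1;
        ob[i + (size_t)outSize * j] = bilin2(warped.data(), H, W, x, y);
      }
    }
    std::copy(ob, ob + (size_t)outSize * outSize,
              ob + (size_t)outSize * outSize);
    std::copy(ob, ob + (size_t)outSize * outSize,
              ob + 2 * (size_t)outSize * outSize);
  }
  out.attr("dim") = IntegerVector::create(outSize, outSize, 3 * B);
  return out;
}
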