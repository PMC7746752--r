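// Compiled phantom renderer: evaluates the nested-ellipsoid head model at
// world points mapped through the inverse of the rigid misalignment, with
// one-voxel partial-volume ramps at every surface.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Ell {
  double cx, cy, cz, ax, ay, az, amin;
};

static inline double alpha_of(const Ell& e, double x, double y, double z,
                              double w) {
  double dx = (x - e.cx) / e.ax, dy = (y - e.cy) / e.ay,
         dz = (z - e.cz) / e.az;
  double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  double a = (1.0 - r) * e.amin / w + 0.5;
  if (a < 0) return 0;
  if (a > 1) return 1;
  return a;
}

// [[Rcpp::export(name = ".phantomRenderC")]]
NumericVector phantomRenderC(IntegerVector dims, NumericVector spacing,
                             NumericMatrix Rinv, NumericVector trans,
                             NumericMatrix ellipsoids,
                             NumericVector intensities, double edgeWidth) {
  // ellipsoids: one row per structure (cx, cy, cz, ax, ay, az); order:
  // brain, shellOuter, shellInner, ventricle, mtlL, mtlR.
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<Ell> E(ellipsoids.nrow());
  for (int r = 0; r < ellipsoids.nrow(); ++r) {
    E[r] = {ellipsoids(r, 0), ellipsoids(r, 1), ellipsoids(r, 2),
            ellipsoids(r, 3), ellipsoids(r, 4), ellipsoids(r, 5),
            std::min(ellipsoids(r, 3),
                     std::min(ellipsoids(r, 4), ellipsoids(r, 5)))};
  }
  NumericVector out((size_t)n1 * n2 * n3);
  double h1 = (n1 - 1) / 2.0, h2 = (n2 - 1) / 2.0, h3 = (n3 - 1) / 2.0;
  size_t idx = 0;
  for (int k = 0; k < n3; ++k) {
    double pz = (k - h3) * spacing[2] - trans[2];
    for (int j = 0; j < n2; ++j) {
      double py = (j - h2) * spacing[1] - trans[1];
      for (int i = 0; i < n1; ++i, ++idx) {
        double px = (i - h1) * spacing[0] - trans[0];
        double qx = Rinv(0, 0) * px + Rinv(0, 1) * py + Rinv(0, 2) * pz;
        double qy = Rinv(1, 0) * px + Rinv(1, 1) * py + Rinv(1, 2) * pz;
        double qz = Rinv(2, 0) * px + Rinv(2, 1) * py + Rinv(2, 2) * pz;
        double v = 0.0;
        double aBrain = alpha_of(E[0], qx, qy, qz, edgeWidth);
        v += aBrain * (intensities[0] - v);
        double aShell = alpha_of(E[1], qx, qy, qz, edgeWidth) *
          (1.0 - alpha_of(E[2], qx, qy, qz, edgeWidth));
        v += aShell * (intensities[1] - v);
        double aVent = alpha_of(E[3], qx, qy, qz, edgeWidth);
        v += aVent * (intensities[2] - v);
        double aL = alpha_of(E[4], qx, qy, qz, edgeWidth);
        v += aL * (intensities[3] - v);
        double aR = alpha_of(E[5], qx, qy, qz, edgeWidth);
        v += aR * (intensities[3] - v);
        out[idx] = v;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
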