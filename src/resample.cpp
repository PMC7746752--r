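// Trilinear resampling kernels shared by registration, phantom alignment
// and 2D slice augmentation. World coordinates place the origin at the
// volume centre: world = (index - (n-1)/2) * spacing, axes in RAS order.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  // x,y,z in 0-based voxel coordinates; zero outside the field of view
  if (x < -1.0 || y < -1.0 || z < -1.0 || x > nx || y > ny || z > nz)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
    }
  }
  return acc;
}

static void euler_matrix(const double* rot_deg, double R[3][3]) {
  // R = Rz * Ry * Rx, angles in degrees
  const double d2r = M_PI / 180.0;
  double cx = std::cos(rot_deg[0] * d2r), sx = std::sin(rot_deg[0] * d2r);
  double cy = std::cos(rot_deg[1] * d2r), sy = std::sin(rot_deg[1] * d2r);
  double cz = std::cos(rot_deg[2] * d2r), sz = std::sin(rot_deg[2] * d2r);
  R[0][0] = cz * cy;  R[0][1] = cz * sy * sx - sz * cx;  R[0][2] = cz * sy * cx + sz * sx;
  R[1][0] = sz * cy;  R[1][1] = sz * sy * sx + cz * cx;  R[1][2] = sz * sy * cx - cz * sx;
  R[2][0] = -sy;      R[2][1] = cy * sx;                 R[2][2] = cy * cx;
}

// Map a fixed-space world point p through the rigid transform
// q = R (p - c) + c + t, then sample the moving volume at q.
// [[Rcpp::export(name = ".resampleRigidC")]]
NumericVector resampleRigidC(NumericVector mov, NumericVector movSpacing,
                             IntegerVector fixedDim, NumericVector fixedSpacing,
                             NumericVector rotDeg, NumericVector transMm,
                             NumericVector centerMm) {
  IntegerVector md = mov.attr("dim");
  int mx = md[0], my = md[1], mz = md[2];
  int fx = fixedDim[0], fy = fixedDim[1], fz = fixedDim[2];
  double R[3][3];
  euler_matrix(rotDeg.begin(), R);
  NumericVector out((size_t)fx * fy * fz);
  const double* mv = mov.begin();
  double hx = (fx - 1) / 2.0, hy = (fy - 1) / 2.0, hz = (fz - 1) / 2.0;
  double mhx = (mx - 1) / 2.0, mhy = (my - 1) / 2.0, mhz = (mz - 1) / 2.0;
  size_t idx = 0;
  for (int k = 0; k < fz; ++k) {
    double pz = (k - hz) * fixedSpacing[2] - centerMm[2];
    for (int j = 0; j < fy; ++j) {
      double py = (j - hy) * fixedSpacing[1] - centerMm[1];
      for (int i = 0; i < fx; ++i, ++idx) {
        double px = (i - hx) * fixedSpacing[0] - centerMm[0];
        double qx = R[0][0] * px + R[0][1] * py + R[0][2] * pz + centerMm[0] + transMm[0];
        double qy = R[1][0] * px + R[1][1] * py + R[1][2] * pz + centerMm[1] + transMm[1];
        double qz = R[2][0] * px + R[2][1] * py + R[2][2] * pz + centerMm[2] + transMm[2];
        out[idx] = sample_trilinear(mv, mx, my, mz,
                                    qx / movSpacing[0] + mhx,
                                    qy / movSpacing[1] + mhy,
                                    qz / movSpacing[2] + mhz);
      }
    }
  }
  out.attr("dim") = fixedDim;
  return out;
}

// Mean squared difference between the fixed volume and the moving volume
// resampled through the rigid transform, without materialising the result.
// [[Rcpp::export(name = ".rigidMsdC")]]
double rigidMsdC(NumericVector fixed, NumericVector fixedSpacing,
                 NumericVector mov, NumericVector movSpacing,
                 NumericVector rotDeg, NumericVector transMm,
                 NumericVector centerMm) {
  IntegerVector fd = fixed.attr("dim");
  IntegerVector md = mov.attr("dim");
  int fx = fd[0], fy = fd[1], fz = fd[2];
  int mx = md[0], my = md[1], mz = md[2];
  double R[3][3];
  euler_matrix(rotDeg.begin(), R);
  const double* fv = fixed.begin();
  const double* mv = mov.begin();
  double hx = (fx - 1) / 2.0, hy = (fy - 1) / 2.0, hz = (fz - 1) / 2.0;
  double mhx = (mx - 1) / 2.0, mhy = (my - 1) / 2.0, mhz = (mz - 1) / 2.0;
  double ss = 0.0;
  size_t idx = 0;
  for (int k = 0; k < fz; ++k) {
    double pz = (k - hz) * fixedSpacing[2] - centerMm[2];
    for (int j = 0; j < fy; ++j) {
      double py = (j - hy) * fixedSpacing[1] - centerMm[1];
      for (int i = 0; i < fx; ++i, ++idx) {
        double px = (i - hx) * fixedSpacing[0] - centerMm[0];
        double qx = R[0][0] * px + R[0][1] * py + R[0][2] * pz + centerMm[0] + transMm[0];
        double qy = R[1][0] * px + R[1][1] * py + R[1][2] * pz + centerMm[1] + transMm[1];
        double qz = R[2][0] * px + R[2][1] * py + R[2][2] * pz + centerMm[2] + transMm[2];
        double s = sample_trilinear(mv, mx, my, mz,
                                    qx / movSpacing[0] + mhx,
                                    qy / movSpacing[1] + mhy,
                                    qz / movSpacing[2] + mhz);
        double d = fv[idx] - s;
        ss += d * d;
      }
    }
  }
  return ss / (double)idx;
}

// Block-mean downsampling by an integer factor (registration pyramid).
// [[Rcpp::export(name = ".downsampleMeanC")]]
NumericVector downsampleMeanC(NumericVector vol, int factor) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = nx / factor, oy = ny / factor, oz = nz / factor;
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double w = 1.0 / (factor * factor * factor);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double acc = 0.0;
        for (int dz = 0; dz < factor; ++dz)
          for (int dy = 0; dy < factor; ++dy)
            for (int dx = 0; dx < factor; ++dx)
              acc += v[(i * factor + dx) +
                       (size_t)nx * ((j * factor + dy) + (size_t)ny * (k * factor + dz))];
        out[i + (size_t)ox * (j + (size_t)oy * k)] = acc * w;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

static inline double sample_bilinear(const double* v, int nx, int ny,
                                     double x, double y) {
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

// 2D similarity warp about the image centre: forward map
// p' = s * R(theta) * (p - c) + c + t; bilinear interpolation, zero fill.
// [[Rcpp::export(name = ".warpAffine2C")]]
NumericMatrix warpAffine2C(NumericMatrix img, double rotDeg, double scale,
                           double tx, double ty) {
  int nx = img.nrow(), ny = img.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double th = rotDeg * M_PI / 180.0;
  double c = std::cos(th), s = std::sin(th);
  // inverse map: p = R^T ((p' - c - t)/s) + c
  NumericMatrix out(nx, ny);
  const double* v = img.begin();
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double ux = (i - cx - tx) / scale, uy = (j - cy - ty) / scale;
      double x = c * ux + s * uy + cx;
      double y = -s * ux + c * uy + cy;
      out(i, j) = sample_bilinear(v, nx, ny, x, y);
    }
  return out;
}

// Bilinear resize with centre-aligned pixel grids.
// [[Rcpp::export(name = ".resizeBilinear2C")]]
NumericMatrix resizeBilinear2C(NumericMatrix img, int outNx, int outNy) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(outNx, outNy);
  const double* v = img.begin();
  double sx = (double)nx / outNx, sy = (double)ny / outNy;
  for (int j = 0; j < outNy; ++j) {
    double y = (j + 0.5) * sy - 0.5;
    for (int i = 0; i < outNx; ++i) {
      double x = (i + 0.5) * sx - 0.5;
      out(i, j) = sample_bilinear(v, nx, ny, x, y);
    }
  }
  return out;
}

static inline double sample_trilinear_grad(const double* v, int nx, int ny,
                                           int nz, double x, double y,
                                           double z, double g[3]) {
  g[0] = g[1] = g[2] = 0.0;
  if (x < -1.0 || y < -1.0 || z < -1.0 || x > nx || y > ny || z > nz)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz, dwz = dz ? 1.0 : -1.0;
    for (int dy = 0; dy < 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy, dwy = dy ? 1.0 : -1.0;
      for (int dx = 0; dx < 2; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx, dwx = dx ? 1.0 : -1.0;
        double val = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        acc += wx * wy * wz * val;
        g[0] += dwx * wy * wz * val;
        g[1] += wx * dwy * wz * val;
        g[2] += wx * wy * dwz * val;
      }
    }
  }
  return acc;
}

// MSD and its analytic gradient w.r.t. the 6 rigid parameters
// (3 rotations in degrees, 3 translations in mm).
// [[Rcpp::export(name = ".rigidMsdGradC")]]
List rigidMsdGradC(NumericVector fixed, NumericVector fixedSpacing,
                   NumericVector mov, NumericVector movSpacing,
                   NumericVector rotDeg, NumericVector transMm,
                   NumericVector centerMm) {
  IntegerVector fd = fixed.attr("dim");
  IntegerVector md = mov.attr("dim");
  int fx = fd[0], fy = fd[1], fz = fd[2];
  int mx = md[0], my = md[1], mz = md[2];
  const double d2r = M_PI / 180.0;
  double rx = rotDeg[0] * d2r, ry = rotDeg[1] * d2r, rz = rotDeg[2] * d2r;
  double cx = std::cos(rx), sx = std::sin(rx);
  double cy = std::cos(ry), sy = std::sin(ry);
  double cz = std::cos(rz), sz = std::sin(rz);
  double R[3][3];
  euler_matrix(rotDeg.begin(), R);
  // derivative matrices of R = Rz Ry Rx w.r.t. each angle (radians)
  double dRx[3][3] = {
    {0, cz * sy * cx + sz * sx, -cz * sy * sx + sz * cx},
    {0, sz * sy * cx - cz * sx, -sz * sy * sx - cz * cx},
    {0, cy * cx, -cy * sx}};
  double dRy[3][3] = {
    {-cz * sy, cz * cy * sx, cz * cy * cx},
    {-sz * sy, sz * cy * sx, sz * cy * cx},
    {-cy, -sy * sx, -sy * cx}};
  double dRz[3][3] = {
    {-sz * cy, -sz * sy * sx - cz * cx, -sz * sy * cx + cz * sx},
    {cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx},
    {0, 0, 0}};
  const double* fv = fixed.begin();
  const double* mv = mov.begin();
  double hx = (fx - 1) / 2.0, hy = (fy - 1) / 2.0, hz = (fz - 1) / 2.0;
  double mhx = (mx - 1) / 2.0, mhy = (my - 1) / 2.0, mhz = (mz - 1) / 2.0;
  double ss = 0.0;
  double grad[6] = {0, 0, 0, 0, 0, 0};
  size_t idx = 0;
  for (int k = 0; k < fz; ++k) {
    double pz = (k - hz) * fixedSpacing[2] - centerMm[2];
    for (int j = 0; j < fy; ++j) {
      double py = (j - hy) * fixedSpacing[1] - centerMm[1];
      for (int i = 0; i < fx; ++i, ++idx) {
        double px = (i - hx) * fixedSpacing[0] - centerMm[0];
        double qx = R[0][0] * px + R[0][1] * py + R[0][2] * pz + centerMm[0] + transMm[0];
        double qy = R[1][0] * px + R[1][1] * py + R[1][2] * pz + centerMm[1] + transMm[1];
        double qz = R[2][0] * px + R[2][1] * py + R[2][2] * pz + centerMm[2] + transMm[2];
        double gv[3];
        double s = sample_trilinear_grad(mv, mx, my, mz,
                                         qx / movSpacing[0] + mhx,
                                         qy / movSpacing[1] + mhy,
                                         qz / movSpacing[2] + mhz, gv);
        double r = fv[idx] - s;
        ss += r * r;
        // dMSD contribution: -2 r * gradM(world) . dq/dp
        double gx = gv[0] / movSpacing[0];
        double gy = gv[1] / movSpacing[1];
        double gz = gv[2] / movSpacing[2];
        double c = -2.0 * r;
        grad[3] += c * gx;
        grad[4] += c * gy;
        grad[5] += c * gz;
        grad[0] += c * d2r * (gx * (dRx[0][0] * px + dRx[0][1] * py + dRx[0][2] * pz) +
                              gy * (dRx[1][0] * px + dRx[1][1] * py + dRx[1][2] * pz) +
                              gz * (dRx[2][0] * px + dRx[2][1] * py + dRx[2][2] * pz));
        grad[1] += c * d2r * (gx * (dRy[0][0] * px + dRy[0][1] * py + dRy[0][2] * pz) +
                              gy * (dRy[1][0] * px + dRy[1][1] * py + dRy[1][2] * pz) +
                              gz * (dRy[2][0] * px + dRy[2][1] * py + dRy[2][2] * pz));
        grad[2] += c * d2r * (gx * (dRz[0][0] * px + dRz[0][1] * py + dRz[0][2] * pz) +
                              gy * (dRz[1][0] * px + dRz[1][1] * py + dRz[1][2] * pz) +
                              gz * (dRz[2][0] * px + dRz[2][1] * py + dRz[2][2] * pz));
      }
    }
  }
  NumericVector g(6);
  for (int t = 0; t < 6; ++t) g[t] = grad[t] / (double)idx;
  return List::create(_["value"] = ss / (double)idx, _["gradient"] = g);
}
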