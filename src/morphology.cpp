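// 3D binary morphology (separable box structuring element) and 6-connected
// component labelling, used by the brain-extraction step.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static void min_filter_axis(std::vector<int>& m, int nx, int ny, int nz,
                            int r, int axis, bool take_min) {
  std::vector<int> src = m;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int best = take_min ? 1 : 0;
        for (int d = -r; d <= r; ++d) {
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii += d; else if (axis == 1) jj += d; else kk += d;
          int val;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            val = 0;  // outside the grid counts as background
          else
            val = src[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          if (take_min) { if (val < best) best = val; }
          else          { if (val > best) best = val; }
        }
        m[i + (size_t)nx * (j + (size_t)ny * k)] = best;
      }
}

static std::vector<int> as_int_mask(const IntegerVector& mask) {
  std::vector<int> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] != 0 ? 1 : 0;
  return m;
}

static IntegerVector wrap_mask(const std::vector<int>& m, const IntegerVector& dim) {
  IntegerVector out(m.size());
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i];
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".binErodeC")]]
IntegerVector binErodeC(IntegerVector mask, int r) {
  IntegerVector dim = mask.attr("dim");
  std::vector<int> m = as_int_mask(mask);
  for (int axis = 0; axis < 3; ++axis)
    min_filter_axis(m, dim[0], dim[1], dim[2], r, axis, true);
  return wrap_mask(m, dim);
}

// [[Rcpp::export(name = ".binDilateC")]]
IntegerVector binDilateC(IntegerVector mask, int r) {
  IntegerVector dim = mask.attr("dim");
  std::vector<int> m = as_int_mask(mask);
  for (int axis = 0; axis < 3; ++axis)
    min_filter_axis(m, dim[0], dim[1], dim[2], r, axis, false);
  return wrap_mask(m, dim);
}

// Largest 6-connected foreground component.
// [[Rcpp::export(name = ".largestComponentC")]]
IntegerVector largestComponentC(IntegerVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int next_label = 0, best_label = 0;
  size_t best_size = 0;
  std::queue<size_t> q;
  for (size_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++next_label;
    size_t sz = 0;
    lab[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      size_t p = q.front(); q.pop();
      ++sz;
      int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        size_t pp = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[pp] != 0 && lab[pp] == 0) {
          lab[pp] = next_label;
          q.push(pp);
        }
      }
    }
    if (sz > best_size) { best_size = sz; best_label = next_label; }
  }
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = lab[i] == best_label && best_label > 0 ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}
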