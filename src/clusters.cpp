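#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 6-connected component labelling of a 3D logical mask (flood fill) and a
// brute-force threshold-free cluster enhancement (TFCE) accumulator.

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t w = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// TFCE(v) = sum over thresholds h (dh-spaced from dh to max) of
// extent(h, v)^E * h^H * dh, with extent the 6-connected component size of
// {stat >= h} containing v.  Plain right-endpoint Riemann sum.

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector dims, double E,
                       double H, double dh_frac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  std::fill(out.begin(), out.end(), 0.0);
  double mx = 0.0;
  for (size_t v = 0; v < n; ++v)
    if (stat[v] > mx) mx = stat[v];
  if (mx <= 0.0) return out;
  const double dh = dh_frac * mx;
  const int nsteps = (int)std::floor(1.0 / dh_frac + 1e-9);

  LogicalVector m(n);
  for (int s = 1; s <= nsteps; ++s) {
    const double h = s * dh;
    bool any = false;
    for (size_t v = 0; v < n; ++v) {
      m[v] = stat[v] >= h;
      any = any || m[v];
    }
    if (!any) break;
    IntegerVector lab = cpp_label3d(m, dims);
    int ncomp = 0;
    for (size_t v = 0; v < n; ++v)
      if (lab[v] > ncomp) ncomp = lab[v];
    std::vector<double> sz(ncomp + 1, 0.0);
    for (size_t v = 0; v < n; ++v)
      if (lab[v]) sz[lab[v]] += 1.0;
    std::vector<double> add(ncomp + 1, 0.0);
    const double hh = std::pow(h, H) * dh;
    for (int c = 1; c <= ncomp; ++c) add[c] = std::pow(sz[c], E) * hh;
    for (size_t v = 0; v < n; ++v)
      if (lab[v]) out[v] += add[lab[v]];
  }
  return out;
}
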