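#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel interpolation between an oversampled Cartesian spectrum and
// non-Cartesian sample locations.  `coords` are fractional indices into the
// *unshifted* FFT spectrum (0 = DC), wrapped periodically.  The separable
// kernel is looked up from a dense precomputed table of half-kernel values
// (argument in [0, width/2], `table_scale` entries per unit).

static inline double kb_lookup(const double *tab, int ntab, double scale,
                               double u) {
  double a = std::fabs(u) * scale;
  int i = (int)a;
  if (i >= ntab - 1) return 0.0;
  double f = a - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// [[Rcpp::export]]
ComplexVector cpp_kb_gather(ComplexVector grid, IntegerVector gdims,
                            NumericMatrix coords, double width,
                            NumericVector table, double table_scale) {
  const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  const int M = coords.nrow();
  const int hw = (int)std::ceil(width / 2.0);
  const double *tab = REAL(table);
  const int ntab = table.size();

  ComplexVector out(M);
  const Rcomplex *gp = COMPLEX(grid);
  Rcomplex *op = COMPLEX(out);
  std::vector<double> wx(2 * hw + 1), wy(2 * hw + 1), wz(2 * hw + 1);
  std::vector<int> ix(2 * hw + 1), iy(2 * hw + 1), iz(2 * hw + 1);

  for (int m = 0; m < M; ++m) {
    const double px = coords(m, 0), py = coords(m, 1), pz = coords(m, 2);
    const int bx = (int)std::floor(px), by = (int)std::floor(py),
              bz = (int)std::floor(pz);
    int nx = 0, ny = 0, nz = 0;
    for (int d = -hw + 1; d <= hw; ++d) {
      double u = bx + d - px;
      if (std::fabs(u) <= width / 2.0) {
        wx[nx] = kb_lookup(tab, ntab, table_scale, u);
        ix[nx++] = ((bx + d) % gx + gx) % gx;
      }
      u = by + d - py;
      if (std::fabs(u) <= width / 2.0) {
        wy[ny] = kb_lookup(tab, ntab, table_scale, u);
        iy[ny++] = ((by + d) % gy + gy) % gy;
      }
      u = bz + d - pz;
      if (std::fabs(u) <= width / 2.0) {
        wz[nz] = kb_lookup(tab, ntab, table_scale, u);
        iz[nz++] = ((bz + d) % gz + gz) % gz;
      }
    }
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < nz; ++c) {
      size_t oz = (size_t)iz[c] * gx * gy;
      for (int b = 0; b < ny; ++b) {
        size_t oy = oz + (size_t)iy[b] * gx;
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < nx; ++a) {
          size_t v = oy + ix[a];
          double w = wx[a] * wyz;
          sr += w * gp[v].r;
          si += w * gp[v].i;
        }
      }
    }
    op[m].r = sr;
    op[m].i = si;
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_kb_scatter(ComplexVector samp, IntegerVector gdims,
                             NumericMatrix coords, double width,
                             NumericVector table, double table_scale) {
  const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  const int M = coords.nrow();
  const int hw = (int)std::ceil(width / 2.0);
  const double *tab = REAL(table);
  const int ntab = table.size();

  ComplexVector out(gx * (size_t)gy * gz);
  std::vector<double> outr(gx * (size_t)gy * gz, 0.0),
      outi(gx * (size_t)gy * gz, 0.0);
  std::vector<double> wx(2 * hw + 1), wy(2 * hw + 1), wz(2 * hw + 1);
  std::vector<int> ix(2 * hw + 1), iy(2 * hw + 1), iz(2 * hw + 1);

  const Rcomplex *sp = COMPLEX(samp);
  for (int m = 0; m < M; ++m) {
    const double sr = sp[m].r, si = sp[m].i;
    const double px = coords(m, 0), py = coords(m, 1), pz = coords(m, 2);
    const int bx = (int)std::floor(px), by = (int)std::floor(py),
              bz = (int)std::floor(pz);
    int nx = 0, ny = 0, nz = 0;
    for (int d = -hw + 1; d <= hw; ++d) {
      double u = bx + d - px;
      if (std::fabs(u) <= width / 2.0) {
        wx[nx] = kb_lookup(tab, ntab, table_scale, u);
        ix[nx++] = ((bx + d) % gx + gx) % gx;
      }
      u = by + d - py;
      if (std::fabs(u) <= width / 2.0) {
        wy[ny] = kb_lookup(tab, ntab, table_scale, u);
        iy[ny++] = ((by + d) % gy + gy) % gy;
      }
      u = bz + d - pz;
      if (std::fabs(u) <= width / 2.0) {
        wz[nz] = kb_lookup(tab, ntab, table_scale, u);
        iz[nz++] = ((bz + d) % gz + gz) % gz;
      }
    }
    for (int c = 0; c < nz; ++c) {
      size_t oz = (size_t)iz[c] * gx * gy;
      for (int b = 0; b < ny; ++b) {
        size_t oy = oz + (size_t)iy[b] * gx;
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < nx; ++a) {
          size_t v = oy + ix[a];
          double w = wx[a] * wyz;
          outr[v] += w * sr;
          outi[v] += w * si;
        }
      }
    }
  }
  Rcomplex *op = COMPLEX(out);
  for (size_t v = 0; v < outr.size(); ++v) {
    op[v].r = outr[v];
    op[v].i = outi[v];
  }
  return out;
}
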