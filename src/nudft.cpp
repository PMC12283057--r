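#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

// Exact type-II non-uniform DFT of a 3D volume at arbitrary k-space
// coordinates, and its adjoint.  Coordinates are in cycles/voxel; the
// spatial origin sits at the grid centre c = floor(dim/2) (0-based).
// Cost is O(M * Nvox) so these are reference operators for small grids;
// the Kaiser-Bessel gridded operator (gridding.cpp + FFT in R) is the
// production path and is validated against these.

// [[Rcpp::export]]
ComplexVector cpp_nudft_forward(ComplexVector img, IntegerVector dims,
                                NumericMatrix coords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int M = coords.nrow();
  const double cx = nx / 2, cy = ny / 2, cz = nz / 2;
  std::vector< std::complex<double> > im(nx * (size_t)ny * nz);
  const Rcomplex *ip = COMPLEX(img);
  for (size_t v = 0; v < im.size(); ++v)
    im[v] = std::complex<double>(ip[v].r, ip[v].i);

  ComplexVector out(M);
  Rcomplex *op = COMPLEX(out);
  std::vector< std::complex<double> > ex(nx), ey(ny), ez(nz);
  std::vector< std::complex<double> > tmp(ny * (size_t)nz);
  const double twopi = 2.0 * M_PI;

  for (int m = 0; m < M; ++m) {
    const double kx = coords(m, 0), ky = coords(m, 1), kz = coords(m, 2);
    for (int i = 0; i < nx; ++i) {
      double ph = -twopi * kx * (i - cx);
      ex[i] = std::complex<double>(std::cos(ph), std::sin(ph));
    }
    for (int j = 0; j < ny; ++j) {
      double ph = -twopi * ky * (j - cy);
      ey[j] = std::complex<double>(std::cos(ph), std::sin(ph));
    }
    for (int k = 0; k < nz; ++k) {
      double ph = -twopi * kz * (k - cz);
      ez[k] = std::complex<double>(std::cos(ph), std::sin(ph));
    }
    // contract x first, then y/z
    std::fill(tmp.begin(), tmp.end(), std::complex<double>(0.0, 0.0));
    size_t v = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        std::complex<double> acc(0.0, 0.0);
        for (int i = 0; i < nx; ++i, ++v) acc += im[v] * ex[i];
        tmp[j + (size_t)ny * k] = acc;
      }
    std::complex<double> s(0.0, 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        s += tmp[j + (size_t)ny * k] * ey[j] * ez[k];
    op[m].r = s.real();
    op[m].i = s.imag();
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_nudft_adjoint(ComplexVector samp, IntegerVector dims,
                                NumericMatrix coords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int M = coords.nrow();
  const double cx = nx / 2, cy = ny / 2, cz = nz / 2;
  const double twopi = 2.0 * M_PI;

  std::vector< std::complex<double> > im(nx * (size_t)ny * nz,
                                         std::complex<double>(0.0, 0.0));
  std::vector< std::complex<double> > ex(nx), ey(ny), ez(nz);

  const Rcomplex *sp = COMPLEX(samp);
  for (int m = 0; m < M; ++m) {
    std::complex<double> s(sp[m].r, sp[m].i);
    const double kx = coords(m, 0), ky = coords(m, 1), kz = coords(m, 2);
    for (int i = 0; i < nx; ++i) {
      double ph = twopi * kx * (i - cx);
      ex[i] = std::complex<double>(std::cos(ph), std::sin(ph));
    }
    for (int j = 0; j < ny; ++j) {
      double ph = twopi * ky * (j - cy);
      ey[j] = std::complex<double>(std::cos(ph), std::sin(ph));
    }
    for (int k = 0; k < nz; ++k) {
      double ph = twopi * kz * (k - cz);
      ez[k] = std::complex<double>(std::cos(ph), std::sin(ph));
    }
    size_t v = 0;
    for (int k = 0; k < nz; ++k) {
      std::complex<double> sz = s * ez[k];
      for (int j = 0; j < ny; ++j) {
        std::complex<double> szy = sz * ey[j];
        for (int i = 0; i < nx; ++i, ++v) im[v] += szy * ex[i];
      }
    }
  }
  ComplexVector out(nx * (size_t)ny * nz);
  Rcomplex *op = COMPLEX(out);
  for (size_t v = 0; v < im.size(); ++v) {
    op[v].r = im[v].real();
    op[v].i = im[v].imag();
  }
  return out;
}
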