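// Exact 3D squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm), separable per axis with anisotropic voxel
// spacing. Seeds are foreground voxels; the result holds, for every voxel,
// the squared distance in mm to the nearest seed's centre.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// one 1D pass: d[i] = min_j ( f[j] + w2 * (i - j)^2 )
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n,
                  double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = (f[v[k]] == INF) ? INF : f[v[k]] + w2 * dq * dq;
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector seed, IntegerVector dims,
                    NumericVector spacing_zyx) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = seed[i] ? 0.0 : INF;
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // array layout is column-major with dims (nz, ny, nx):
  // index = z + nz * (y + ny * x)
  // pass along z
  double w2 = spacing_zyx[0] * spacing_zyx[0];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) f[q] = out[base + q];
      edt1d(f, d, v, z, nz, w2);
      for (int q = 0; q < nz; ++q) out[base + q] = d[q];
    }
  // pass along y
  w2 = spacing_zyx[1] * spacing_zyx[1];
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)nz * q];
      edt1d(f, d, v, z, ny, w2);
      for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)nz * q] = d[q];
    }
  // pass along x
  w2 = spacing_zyx[2] * spacing_zyx[2];
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; ++q) f[q] = out[base + sx * q];
      edt1d(f, d, v, z, nx, w2);
      for (int q = 0; q < nx; ++q) out[base + sx * q] = d[q];
    }
  return out;
}
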