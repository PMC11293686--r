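#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared 1D distance transform (lower envelope of parabolas) with a
// per-axis sampling step `s` (anisotropic voxels). `f` holds squared
// distances; large finite INF avoids inf-inf NaNs in the intersection.
static const double EDT_INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double s) {
  const int n = (int)f.size();
  const double s2 = s * s;
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double inter;
    for (;;) {
      int p = v[k];
      inter = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
              (2.0 * s2 * (q - p));
      if (inter <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (double)(q - p) * (double)(q - p) + f[p];
  }
}

// Exact anisotropic Euclidean distance transform of a 3D logical array
// (column-major, dim = c(ny, nx, nz)). Returns, for every TRUE voxel, the
// distance (in physical units given by `spacing` = c(sy, sx, sz)) to the
// centre of the nearest FALSE voxel; 0 for FALSE voxels. Voxels beyond the
// array border are not treated as background.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  const R_xlen_t ntot = (R_xlen_t)ny * nx * nz;
  NumericVector out(ntot);

  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = mask[i] ? EDT_INF : 0.0;

  const int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along y (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j) {
      R_xlen_t base = (R_xlen_t)k * ny * nx + (R_xlen_t)j * ny;
      for (int i = 0; i < ny; ++i) f[i] = out[base + i];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, v, z, sy);
      for (int i = 0; i < ny; ++i) out[base + i] = d[i];
      f.resize(nmax); d.resize(nmax);
    }

  // pass along x (stride ny)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < ny; ++i) {
      R_xlen_t base = (R_xlen_t)k * ny * nx + i;
      for (int j = 0; j < nx; ++j) f[j] = out[base + (R_xlen_t)j * ny];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, z, sx);
      for (int j = 0; j < nx; ++j) out[base + (R_xlen_t)j * ny] = d[j];
      f.resize(nmax); d.resize(nmax);
    }

  // pass along z (stride ny*nx)
  const R_xlen_t strz = (R_xlen_t)ny * nx;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      R_xlen_t base = (R_xlen_t)j * ny + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * strz];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, v, z, sz);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * strz] = d[k];
      f.resize(nmax); d.resize(nmax);
    }

  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = (out[i] >= EDT_INF) ? R_PosInf : std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
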