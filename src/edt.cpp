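#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher, lower-envelope-of-parabolas), 1D pass.
// f: input squared distances sampled at positions step*0..n-1; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n, 0);
  std::vector<double> z(n + 1, 0.0);
  int k = -1; // index of the rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // only finite parabolas enter the envelope
    double qq = q * step;
    double s = 0.0;
    while (k >= 0) {
      double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no set voxel on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (z[kk + 1] < qq) ++kk;
    double vv = v[kk] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[kk]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// set voxel center of `mask`, on an axis-aligned anisotropic grid.
// Returns +Inf everywhere when the mask is empty.
// [[Rcpp::export]]
Rcpp::NumericVector edt_squared_mm2(Rcpp::LogicalVector mask,
                                    Rcpp::IntegerVector dims,
                                    Rcpp::NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const double sx = spacing[0], sy = spacing[1],
               sz = spacing.size() > 2 ? spacing[2] : 1.0;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;

  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, sx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, sy);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }

  // pass along z
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    const R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * plane];
        dt1d(f, d, nz, sz);
        for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * plane] = d[z];
      }
  }
  return out;
}
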