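#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2004):
// lower envelope of the parabolas f[q] + (x - q*w)^2, sampled at the grid
// points. f holds squared distances along one line; w is the spacing in mm.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; q++) {
    double xq = q * w;
    double s;
    for (;;) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) k--;
      else break;
    }
    if (s <= z[k]) { // k == 0: new parabola dominates everywhere
      v[0] = q;
      z[0] = -1e300;
      z[1] = 1e300;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
      z[k + 1] = 1e300;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; q++) f[q] = d[q];
}

// Exact squared Euclidean distance (mm^2) to the nearest TRUE voxel, by three
// separable 1-D passes. Background voxels start at a finite sentinel far above
// any attainable squared grid distance, so no infinity bookkeeping is needed;
// the caller guarantees a non-empty mask.
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dim,
                          NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  const double BIG = 16.0 * (ex * ex + ey * ey + ez * ez) + 1.0;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); i++)
    out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k = 0; k < nz; k++) // pass along x
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = f[i];
    }
  for (int k = 0; k < nz; k++) // pass along y
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = f[j];
    }
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++) // pass along z
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nxy] = f[k];
    }
  return out;
}
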