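#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Large finite sentinel instead of +Inf so the parabola intersections in
// dt1d stay well defined; real squared distances on any sane grid are many
// orders of magnitude below it.
static const double BIG = 1e15;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher, lower
// envelope of parabolas). `f` holds squared distances so far, `step` the
// physical sample spacing along this axis.
static void dt1d(const double* f, double* d, int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      double qq = q * step, vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (k > 0 && s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (z[k + 1] < qq) ++k;
    double diff = qq - v[k] * step;
    d[q] = diff * diff + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest TRUE voxel of a 3-D mask,
// in physical units given per-axis spacing. Voxels of an all-FALSE mask get
// a large sentinel value (>= 1e15).
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> res(buf.size());

  // axis 1 (x, fastest varying)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t off = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) buf[x] = out[off + x];
      dt1d(buf.data(), res.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[off + x] = res[x];
    }

  // axis 2 (y)
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t off = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) buf[y] = out[off + (R_xlen_t)y * nx];
      dt1d(buf.data(), res.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[off + (R_xlen_t)y * nx] = res[y];
    }

  // axis 3 (z)
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t off = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) buf[z] = out[off + z * nxy];
      dt1d(buf.data(), res.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[off + z * nxy] = res[z];
    }

  return out;
}
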