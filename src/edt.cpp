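// Exact anisotropic squared Euclidean distance transform on a 3-D voxel
// grid, by the separable lower-envelope (parabola) algorithm applied once
// per axis. Complexity O(N) per axis; spacing may differ per axis.
#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double EDT_INF = 1e30;

// One 1-D pass: d[q] = min_i ( (w*(q-i))^2 + f[i] ).
static void dt1d(const double* f, double* d, int* v, double* z,
                 int n, double w) {
  double w2 = w * w;
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;   // true infinities: intersection abscissas of parabolas
  z[1] = INF;    // with capped heights can exceed any finite sentinel
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + w2 * (double)q * q;
    double s;
    while (true) {
      int p = v[k];
      s = (fq - (f[p] + w2 * (double)p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector feature, IntegerVector dim,
                              NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // init: 0 at feature voxels, "infinity" elsewhere
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (feature[i] == TRUE) ? 0.0 : EDT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k3 = 0; k3 < nz; ++k3)
    for (int k2 = 0; k2 < ny; ++k2) {
      double* line = &out[(R_xlen_t)k3 * nx * ny + (R_xlen_t)k2 * nx];
      for (int i = 0; i < nx; ++i) f[i] = line[i];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, spacing[0]);
      for (int i = 0; i < nx; ++i) line[i] = d[i];
    }
  // pass along y
  for (int k3 = 0; k3 < nz; ++k3)
    for (int k1 = 0; k1 < nx; ++k1) {
      R_xlen_t base = (R_xlen_t)k3 * nx * ny + k1;
      for (int i = 0; i < ny; ++i) f[i] = out[base + (R_xlen_t)i * nx];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[1]);
      for (int i = 0; i < ny; ++i) out[base + (R_xlen_t)i * nx] = d[i];
    }
  // pass along z
  R_xlen_t planesz = (R_xlen_t)nx * ny;
  for (int k2 = 0; k2 < ny; ++k2)
    for (int k1 = 0; k1 < nx; ++k1) {
      R_xlen_t base = (R_xlen_t)k2 * nx + k1;
      for (int i = 0; i < nz; ++i) f[i] = out[base + (R_xlen_t)i * planesz];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2]);
      for (int i = 0; i < nz; ++i) out[base + (R_xlen_t)i * planesz] = d[i];
    }

  // anything still near EDT_INF had no feature voxel at all
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= EDT_INF) out[i] = R_PosInf;
  return out;
}
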