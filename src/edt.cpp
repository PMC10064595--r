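#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic 3D lattice,
// separable lower-envelope algorithm (Felzenszwalb & Huttenlocher 2012).
// Distances are measured between voxel centers in physical units.

static const double BIG = 1e20;

// 1D squared-distance transform along a line of n samples spaced `step`
// apart. f holds input squared distances, d receives the output.
static void dt1d(const double* f, double* d, int n, double step,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double qs = q * step;
    double s;
    while (true) {
      double vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (s <= z[k]) {
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
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector sites, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = sites[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* line = &d[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx];
      for (int i = 0; i < nx; ++i) f[i] = line[i];
      dt1d(f.data(), out.data(), nx, spacing[0], v.data(), z.data());
      for (int i = 0; i < nx; ++i) line[i] = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = &d[(R_xlen_t)k * nx * ny + i];
      for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)j * nx];
      dt1d(f.data(), out.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)j * nx] = out[j];
    }
  // pass along z
  const R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = &d[(R_xlen_t)j * nx + i];
      for (int k = 0; k < nz; ++k) f[k] = base[(R_xlen_t)k * slab];
      dt1d(f.data(), out.data(), nz, spacing[2], v.data(), z.data());
      for (int k = 0; k < nz; ++k) base[(R_xlen_t)k * slab] = out[k];
    }
  return d;
}

// Exact maximum pairwise Euclidean distance over a set of 3D points.
// [[Rcpp::export(name = ".max_pairwise_dist_cpp")]]
double max_pairwise_dist_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int a = 0; a < n; ++a) {
    const double xa = pts(a, 0), ya = pts(a, 1), za = pts(a, 2);
    for (int b = a + 1; b < n; ++b) {
      const double dx = pts(b, 0) - xa, dy = pts(b, 1) - ya,
                   dz = pts(b, 2) - za;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}
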