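// Exact Euclidean distance transform for 3D binary masks with anisotropic
// voxel spacing, via the separable squared-distance algorithm of
// Felzenszwalb & Huttenlocher (lower envelope of parabolas per axis).

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform along samples spaced w apart.
// f: squared distances in/out; n: length; scratch vectors provided.
static void dt1d(std::vector<double> &f, int n, double w,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  const double w2 = w * w;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) return; // nothing reachable along this line
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabola never forms the envelope
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      s = ((fq + w2 * q * q) - (fv + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (k > 0 && s <= z[k]) {
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
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t off = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      bool any = false;
      for (int i = 0; i < n1; ++i) { f[i] = g[off + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, n1, spacing[0], d, v, z);
      for (int i = 0; i < n1; ++i) g[off + i] = f[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t off = (R_xlen_t)k * n1 * n2 + i;
      bool any = false;
      for (int j = 0; j < n2; ++j) { f[j] = g[off + (R_xlen_t)j * n1]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, n2, spacing[1], d, v, z);
      for (int j = 0; j < n2; ++j) g[off + (R_xlen_t)j * n1] = f[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t off = (R_xlen_t)j * n1 + i;
      bool any = false;
      for (int k = 0; k < n3; ++k) { f[k] = g[off + (R_xlen_t)k * n1 * n2]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, n3, spacing[2], d, v, z);
      for (int k = 0; k < n3; ++k) g[off + (R_xlen_t)k * n1 * n2] = f[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
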