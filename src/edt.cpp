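// Exact anisotropic squared Euclidean distance transform (lower-envelope
// parabola algorithm), applied axis by axis. Used to compute distances
// from every voxel centre to the nearest site (surface) voxel centre in mm.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

namespace {

// large finite sentinel: keeps parabola intersections finite while being
// dominated by any real squared distance
const double BIG = 1e100;

// 1D squared distance transform on samples at positions i * s (in place).
void dt1d(std::vector<double>& f, int n, double s,
          std::vector<double>& d, std::vector<int>& v,
          std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sec = ((f[q] + xq * xq) - (f[v[k]] + (v[k] * s) * (v[k] * s))) /
                 (2.0 * xq - 2.0 * v[k] * s);
    while (sec <= z[k]) {
      --k;
      sec = ((f[q] + xq * xq) - (f[v[k]] + (v[k] * s) * (v[k] * s))) /
            (2.0 * xq - 2.0 * v[k] * s);
    }
    ++k;
    v[k] = q;
    z[k] = sec;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

} // namespace

// [[Rcpp::export(name = ".edt_to_sites")]]
Rcpp::NumericVector edt_to_sites(Rcpp::LogicalVector sites,
                                 Rcpp::NumericVector spacing) {
  Rcpp::IntegerVector dim = sites.attr("dim");
  if (dim.size() != 3) Rcpp::stop("sites must be a 3D array");
  if (spacing.size() != 3) Rcpp::stop("spacing must have 3 components");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<double> g(static_cast<size_t>(n1) * n2 * n3);
  bool any_site = false;
  for (size_t i = 0; i < g.size(); ++i) {
    g[i] = sites[i] ? 0.0 : BIG;
    if (sites[i]) any_site = true;
  }
  if (!any_site) Rcpp::stop("site mask is empty");

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  auto pass = [&](int n, double s, size_t stride, size_t nlines,
                  auto line_start) {
    for (size_t ln = 0; ln < nlines; ++ln) {
      size_t base = line_start(ln);
      for (int i = 0; i < n; ++i) f[i] = g[base + i * stride];
      dt1d(f, n, s, d, v, z);
      for (int i = 0; i < n; ++i) g[base + i * stride] = f[i];
    }
  };

  // axis 1 (fastest-varying), then axis 2, then axis 3
  pass(n1, spacing[0], 1, static_cast<size_t>(n2) * n3,
       [&](size_t ln) { return ln * n1; });
  pass(n2, spacing[1], n1, static_cast<size_t>(n1) * n3,
       [&](size_t ln) {
         size_t i1 = ln % n1, i3 = ln / n1;
         return i1 + i3 * static_cast<size_t>(n1) * n2;
       });
  pass(n3, spacing[2], static_cast<size_t>(n1) * n2,
       static_cast<size_t>(n1) * n2,
       [&](size_t ln) { return ln; });

  Rcpp::NumericVector out(g.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
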