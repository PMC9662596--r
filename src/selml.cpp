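#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cross L1 (Manhattan) distance matrix between rows of A and rows of B.
// [[Rcpp::export]]
NumericMatrix cpp_l1_cross(NumericMatrix A, NumericMatrix B) {
  if (A.ncol() != B.ncol())
    stop("representation length mismatch: %d vs %d columns", A.ncol(), B.ncol());
  const int na = A.nrow(), nb = B.nrow(), p = A.ncol();
  NumericMatrix D(na, nb);
  for (int j = 0; j < nb; ++j) {
    for (int i = 0; i < na; ++i) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += std::fabs(A(i, k) - B(j, k));
      D(i, j) = s;
    }
  }
  return D;
}

static inline double gauss_pdf(double x, double mu, double sigma) {
  const double z = (x - mu) / sigma;
  return std::exp(-0.5 * z * z) / (sigma * 2.5066282746310002); // sqrt(2*pi)
}

// SLATM-style spectrum for one molecule.
// z:        nuclear charges (length n)
// coords:   n x 3 Cartesian coordinates, Angstrom
// basis_z:  elements of the basis, ascending
// pairs:    npair x 2 (z_a <= z_b), canonical order
// triples:  ntrip x 3 (z_a, z_b, z_center), canonical order
// rgrid:    radial grid; tgrid: angular grid over [0, pi]
// Layout: [1-body | per-pair radial blocks | per-triple angular blocks].
// [[Rcpp::export]]
NumericVector cpp_slatm(IntegerVector z, NumericMatrix coords,
                        IntegerVector basis_z, IntegerMatrix pairs,
                        IntegerMatrix triples, NumericVector rgrid,
                        double sigma_r, double dr, NumericVector tgrid,
                        double sigma_t, double dt, double rcut) {
  const int n = z.size();
  const int nel = basis_z.size(), npair = pairs.nrow(), ntrip = triples.nrow();
  const int nr = rgrid.size(), nt = tgrid.size();
  NumericVector out(nel + npair * nr + ntrip * nt);

  // element -> basis index
  std::map<int, int> eidx;
  for (int e = 0; e < nel; ++e) eidx[basis_z[e]] = e;
  for (int i = 0; i < n; ++i)
    if (eidx.find(z[i]) == eidx.end())
      stop("element with nuclear charge %d is not in the basis", z[i]);

  // 1-body: per-element count times nuclear charge
  for (int i = 0; i < n; ++i) out[eidx[z[i]]] += (double)z[i];

  // pair (a<=b) -> pair index
  std::map<std::pair<int, int>, int> pidx;
  for (int p = 0; p < npair; ++p)
    pidx[std::make_pair(pairs(p, 0), pairs(p, 1))] = p;
  // triple (a<=b, center) -> triple index
  std::map<std::pair<std::pair<int, int>, int>, int> tidx;
  for (int t = 0; t < ntrip; ++t)
    tidx[std::make_pair(std::make_pair(triples(t, 0), triples(t, 1)),
                        triples(t, 2))] = t;

  // pairwise distances
  NumericMatrix dist(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      dist(i, j) = dist(j, i) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }

  // 2-body: Gaussian at r_ij on the radial grid, London-style weight
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double r = dist(i, j);
      if (r <= 0) stop("coincident atoms %d and %d", i + 1, j + 1);
      int a = std::min(z[i], z[j]), b = std::max(z[i], z[j]);
      const int p = pidx[std::make_pair(a, b)];
      const double w = 0.5 * z[i] * z[j] / std::pow(r, 6.0) * dr;
      const int off = nel + p * nr;
      for (int k = 0; k < nr; ++k) {
        if (std::fabs(rgrid[k] - r) > 8.0 * sigma_r) continue;
        out[off + k] += w * gauss_pdf(rgrid[k], r, sigma_r);
      }
    }

  // 3-body: Gaussian in the angle at the central atom, Z-weighted
  for (int j = 0; j < n; ++j) {
    std::vector<int> nb;
    for (int i = 0; i < n; ++i)
      if (i != j && dist(i, j) <= rcut) nb.push_back(i);
    const int m = (int)nb.size();
    for (int u = 0; u < m; ++u)
      for (int v = u + 1; v < m; ++v) {
        const int i = nb[u], k = nb[v];
        double ax = coords(i, 0) - coords(j, 0);
        double ay = coords(i, 1) - coords(j, 1);
        double az = coords(i, 2) - coords(j, 2);
        double bx = coords(k, 0) - coords(j, 0);
        double by = coords(k, 1) - coords(j, 1);
        double bz = coords(k, 2) - coords(j, 2);
        double cosv = (ax * bx + ay * by + az * bz) / (dist(i, j) * dist(k, j));
        if (cosv > 1.0) cosv = 1.0;
        if (cosv < -1.0) cosv = -1.0;
        const double theta = std::acos(cosv);
        int a = std::min(z[i], z[k]), b = std::max(z[i], z[k]);
        const int t = tidx[std::make_pair(std::make_pair(a, b), z[j])];
        const double w = (double)z[i] * z[j] * z[k] / 3.0 * dt;
        const int off = nel + npair * nr + t * nt;
        for (int q = 0; q < nt; ++q)
          out[off + q] += w * gauss_pdf(tgrid[q], theta, sigma_t);
      }
  }
  return out;
}
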