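#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform cell list over a fixed point set.  Query points need not lie
// inside the covered box; cell indices are clamped.
struct CellList {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector< std::vector<int> > bins;

  CellList(const NumericMatrix &p, double cell_) : cell(cell_) {
    const int n = p.nrow();
    double mnx = R_PosInf, mny = R_PosInf, mnz = R_PosInf;
    double mxx = R_NegInf, mxy = R_NegInf, mxz = R_NegInf;
    for (int i = 0; i < n; ++i) {
      mnx = std::min(mnx, p(i, 0)); mxx = std::max(mxx, p(i, 0));
      mny = std::min(mny, p(i, 1)); mxy = std::max(mxy, p(i, 1));
      mnz = std::min(mnz, p(i, 2)); mxz = std::max(mxz, p(i, 2));
    }
    if (n == 0) { mnx = mny = mnz = 0.0; mxx = mxy = mxz = 0.0; }
    ox = mnx; oy = mny; oz = mnz;
    nx = std::max(1, (int)std::floor((mxx - ox) / cell) + 1);
    ny = std::max(1, (int)std::floor((mxy - oy) / cell) + 1);
    nz = std::max(1, (int)std::floor((mxz - oz) / cell) + 1);
    bins.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int i = 0; i < n; ++i)
      bins[key(cx(p(i, 0)), cy(p(i, 1)), cz(p(i, 2)))].push_back(i);
  }
  inline int clampi(int c, int nmax) const {
    return c < 0 ? 0 : (c >= nmax ? nmax - 1 : c);
  }
  inline int cx(double x) const { return clampi((int)std::floor((x - ox) / cell), nx); }
  inline int cy(double y) const { return clampi((int)std::floor((y - oy) / cell), ny); }
  inline int cz(double z) const { return clampi((int)std::floor((z - oz) / cell), nz); }
  inline size_t key(int ix, int iy, int iz) const {
    return ((size_t)ix * ny + iy) * nz + iz;
  }
  // collect candidate point indices within `radius` of (x,y,z), exact test
  // left to the caller; cells overlapping the radius ball are enumerated.
  template <typename F>
  void for_candidates(double x, double y, double z, double radius, F fun) const {
    int x0 = clampi((int)std::floor((x - radius - ox) / cell), nx);
    int x1 = clampi((int)std::floor((x + radius - ox) / cell), nx);
    int y0 = clampi((int)std::floor((y - radius - oy) / cell), ny);
    int y1 = clampi((int)std::floor((y + radius - oy) / cell), ny);
    int z0 = clampi((int)std::floor((z - radius - oz) / cell), nz);
    int z1 = clampi((int)std::floor((z + radius - oz) / cell), nz);
    for (int ix = x0; ix <= x1; ++ix)
      for (int iy = y0; iy <= y1; ++iy)
        for (int iz = z0; iz <= z1; ++iz) {
          const std::vector<int> &b = bins[key(ix, iy, iz)];
          for (size_t t = 0; t < b.size(); ++t) fun(b[t]);
        }
  }
};

static inline double lj_pair(double r, double rsum, double seps) {
  double q = rsum / r;
  double q3 = q * q * q;
  double s6 = q3 * q3;
  return seps * (s6 * s6 - 2.0 * s6);
}

// Lennard-Jones 6-12 probe energies: for each probe, sum the pair energy
// over atoms within `cutoff` (boundary inclusive).
// [[Rcpp::export]]
NumericVector probe_energies_cpp(NumericMatrix probes, NumericMatrix atoms,
                                 NumericVector atom_r, NumericVector atom_eps,
                                 double probe_r, double probe_eps,
                                 double cutoff) {
  const int np = probes.nrow(), na = atoms.nrow();
  NumericVector out(np);
  if (na == 0) return out;
  std::vector<double> rsum(na), seps(na);
  for (int j = 0; j < na; ++j) {
    rsum[j] = probe_r + atom_r[j];
    seps[j] = std::sqrt(probe_eps * atom_eps[j]);
  }
  CellList cl(atoms, std::max(cutoff, 1e-6));
  const double cut2 = cutoff * cutoff;
  for (int i = 0; i < np; ++i) {
    double x = probes(i, 0), y = probes(i, 1), z = probes(i, 2);
    double e = 0.0;
    cl.for_candidates(x, y, z, cutoff, [&](int j) {
      double dx = atoms(j, 0) - x, dy = atoms(j, 1) - y, dz = atoms(j, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= cut2 && d2 > 0.0)
        e += lj_pair(std::sqrt(d2), rsum[j], seps[j]);
    });
    out[i] = e;
  }
  return out;
}

// Per-probe score components for the weighted probe score
//   E_i = sum_j ( w1 * E_ij + w2 * C_j + w3 * E_ij * C_j )
// over atoms j within `cutoff`.  C_j is the conservation score of atom j's
// residue when that residue has at least one atom within `cons_cutoff` of
// the probe and 0 otherwise; when gate_cross is FALSE only the bare
// conservation term is distance-gated and the cross term uses C over the
// full energy cutoff.  Returns n x 3 matrix (sum E, sum C, sum E*C).
// [[Rcpp::export]]
NumericMatrix score_components_cpp(NumericMatrix probes, NumericMatrix atoms,
                                   NumericVector atom_r, NumericVector atom_eps,
                                   IntegerVector atom_res, NumericVector res_c,
                                   double probe_r, double probe_eps,
                                   double cutoff, double cons_cutoff,
                                   bool gate_cross) {
  const int np = probes.nrow(), na = atoms.nrow();
  const int nres = res_c.size();
  NumericMatrix out(np, 3);
  if (na == 0) return out;
  std::vector<double> rsum(na), seps(na);
  for (int j = 0; j < na; ++j) {
    rsum[j] = probe_r + atom_r[j];
    seps[j] = std::sqrt(probe_eps * atom_eps[j]);
  }
  CellList cl(atoms, std::max(cutoff, 1e-6));
  const double cut2 = cutoff * cutoff, ccut2 = cons_cutoff * cons_cutoff;
  std::vector<char> near_res(nres, 0);
  std::vector<int> touched;
  std::vector<int> idx;
  std::vector<double> evdw;
  for (int i = 0; i < np; ++i) {
    double x = probes(i, 0), y = probes(i, 1), z = probes(i, 2);
    idx.clear(); evdw.clear(); touched.clear();
    cl.for_candidates(x, y, z, cutoff, [&](int j) {
      double dx = atoms(j, 0) - x, dy = atoms(j, 1) - y, dz = atoms(j, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= cut2 && d2 > 0.0) {
        idx.push_back(j);
        evdw.push_back(lj_pair(std::sqrt(d2), rsum[j], seps[j]));
        int r = atom_res[j] - 1;
        if (d2 <= ccut2 && r >= 0 && r < nres && !near_res[r]) {
          near_res[r] = 1;
          touched.push_back(r);
        }
      }
    });
    double se = 0.0, sc = 0.0, sec = 0.0;
    for (size_t t = 0; t < idx.size(); ++t) {
      int j = idx[t], r = atom_res[j] - 1;
      double e = evdw[t];
      se += e;
      bool gated = (r >= 0 && r < nres && near_res[r]);
      double c = (r >= 0 && r < nres) ? res_c[r] : 0.0;
      if (gated) sc += c;
      if (gate_cross ? gated : true) sec += e * c;
    }
    out(i, 0) = se; out(i, 1) = sc; out(i, 2) = sec;
    for (size_t t = 0; t < touched.size(); ++t) near_res[touched[t]] = 0;
  }
  return out;
}

// For each row of `query`, TRUE when any row of `points` lies within
// `radius` (boundary inclusive).
// [[Rcpp::export]]
LogicalVector near_points_cpp(NumericMatrix points, NumericMatrix query,
                              double radius) {
  const int nq = query.nrow();
  LogicalVector out(nq);
  if (points.nrow() == 0) return out;
  CellList cl(points, std::max(radius, 1e-6));
  const double r2 = radius * radius;
  for (int i = 0; i < nq; ++i) {
    double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    bool hit = false;
    cl.for_candidates(x, y, z, radius, [&](int j) {
      if (hit) return;
      double dx = points(j, 0) - x, dy = points(j, 1) - y, dz = points(j, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= r2) hit = true;
    });
    out[i] = hit;
  }
  return out;
}

// Number of (a, b) point pairs within `radius` (boundary inclusive).
// [[Rcpp::export]]
int count_contacts_cpp(NumericMatrix a, NumericMatrix b, double radius) {
  if (a.nrow() == 0 || b.nrow() == 0) return 0;
  CellList cl(b, std::max(radius, 1e-6));
  const double r2 = radius * radius;
  int n = 0;
  for (int i = 0; i < a.nrow(); ++i) {
    double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    cl.for_candidates(x, y, z, radius, [&](int j) {
      double dx = b(j, 0) - x, dy = b(j, 1) - y, dz = b(j, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= r2) ++n;
    });
  }
  return n;
}
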