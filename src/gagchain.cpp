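// Compiled kernels: NeRF chain realization, restrained potential energy
// with analytic gradient, and nonphysical-geometry detection (overlapping
// bond segments, bonds piercing ring surfaces).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// sequential placement from internal coordinates; rows with a == NA (0)
// are seed rows (1-based indices; idx order defines placement order)
// [[Rcpp::export(name = ".nerf_realize")]]
NumericMatrix nerf_realize(IntegerVector idx, IntegerVector a,
                           IntegerVector b, IntegerVector c,
                           NumericVector bond, NumericVector angle,
                           NumericVector torsion, int n_atoms) {
  NumericMatrix out(n_atoms, 3);
  std::vector<double> X(3 * n_atoms, NA_REAL);
  int nseed = 0;
  int seed_idx[3] = {0, 0, 0};
  for (int r = 0; r < idx.size(); ++r) {
    int i = idx[r] - 1;
    if (a[r] == NA_INTEGER) {
      if (nseed == 0) {
        X[3 * i] = 0; X[3 * i + 1] = 0; X[3 * i + 2] = 0;
      } else if (nseed == 1) {
        X[3 * i] = bond[r]; X[3 * i + 1] = 0; X[3 * i + 2] = 0;
      } else {
        double th = angle[r] * DEG;
        int p = seed_idx[1];
        X[3 * i] = X[3 * p] - bond[r] * std::cos(th);
        X[3 * i + 1] = bond[r] * std::sin(th);
        X[3 * i + 2] = 0;
      }
      if (nseed < 3) seed_idx[nseed] = i;
      ++nseed;
      continue;
    }
    const double* A = &X[3 * (a[r] - 1)];
    const double* B = &X[3 * (b[r] - 1)];
    const double* C = &X[3 * (c[r] - 1)];
    double bc[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
    double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double nbc = norm3(bc);
    for (int k = 0; k < 3; ++k) bc[k] /= nbc;
    double n[3];
    cross3(ab, bc, n);
    double nn = norm3(n);
    if (nn < 1e-10) stop("nerf_realize: collinear frame at row %d", r + 1);
    for (int k = 0; k < 3; ++k) n[k] /= nn;
    double m[3];
    cross3(n, bc, m);
    double th = angle[r] * DEG, ph = torsion[r] * DEG;
    double d0 = -bond[r] * std::cos(th);
    double d1 = bond[r] * std::sin(th) * std::cos(ph);
    double d2 = bond[r] * std::sin(th) * std::sin(ph);
    int i3 = 3 * i;
    for (int k = 0; k < 3; ++k) {
      X[i3 + k] = C[k] + d0 * bc[k] + d1 * m[k] + d2 * n[k];
    }
  }
  for (int i = 0; i < n_atoms; ++i) {
    out(i, 0) = X[3 * i]; out(i, 1) = X[3 * i + 1]; out(i, 2) = X[3 * i + 2];
  }
  return out;
}

// ---- restrained potential ------------------------------------------------

// cell-list neighbour iteration (flat head/next lists to avoid per-call
// allocation of nested containers)
struct CellList {
  int dim[3];
  double lo[3];
  double cell;
  std::vector<int> head;
  std::vector<int> nxt;
  void build(const std::vector<double>& X, int n, double cutoff) {
    cell = cutoff;
    double hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = 1e30; hi[k] = -1e30; }
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], X[3 * i + k]);
        hi[k] = std::max(hi[k], X[3 * i + k]);
      }
    }
    // grow cells if the grid would dwarf the atom count
    double vol = 1.0;
    for (int k = 0; k < 3; ++k) vol *= std::max(cell, hi[k] - lo[k]);
    double target = std::max(64.0, 8.0 * n);
    double min_cell = std::cbrt(vol / target);
    if (min_cell > cell) cell = min_cell;
    for (int k = 0; k < 3; ++k) {
      dim[k] = std::max(1, (int)((hi[k] - lo[k]) / cell) + 1);
    }
    head.assign((size_t)dim[0] * dim[1] * dim[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(&X[3 * i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  int cell_of(const double* p) const {
    int cx = std::min(dim[0] - 1, std::max(0, (int)((p[0] - lo[0]) / cell)));
    int cy = std::min(dim[1] - 1, std::max(0, (int)((p[1] - lo[1]) / cell)));
    int cz = std::min(dim[2] - 1, std::max(0, (int)((p[2] - lo[2]) / cell)));
    return (cx * dim[1] + cy) * dim[2] + cz;
  }
};

// energy + gradient of the restrained potential:
//   bonds:    kb * (b - b0)^2 over all topology bonds
//   angles:   ka * (th - th0)^2 (rad) restrained at constructed values
//   torsions: kt * wrap(ph - ph0)^2 (rad) restrained at constructed values
//   repulsion: eps * ((rmin/r)^6 - 1)^2 for r < rmin, pairs more than
//              3 bonds apart
// [[Rcpp::export(name = ".gag_energy")]]
List gag_energy(NumericVector x, IntegerMatrix bonds, NumericVector b0,
                double kb, IntegerMatrix angles, NumericVector th0,
                double ka, IntegerMatrix tors, NumericVector ph0,
                double kt, NumericVector excl_keys, double eps, double rmin,
                bool want_grad) {
  int n = x.size() / 3;
  std::vector<double> X(x.begin(), x.end());
  std::vector<double> G(3 * n, 0.0);
  double e_bond = 0, e_angle = 0, e_tors = 0, e_rep = 0;

  for (int r = 0; r < bonds.nrow(); ++r) {
    int i = bonds(r, 0) - 1, j = bonds(r, 1) - 1;
    double d[3] = {X[3 * i] - X[3 * j], X[3 * i + 1] - X[3 * j + 1],
                   X[3 * i + 2] - X[3 * j + 2]};
    double b = norm3(d);
    double db = b - b0[r];
    e_bond += kb * db * db;
    if (want_grad && b > 1e-12) {
      double f = 2 * kb * db / b;
      for (int k = 0; k < 3; ++k) {
        G[3 * i + k] += f * d[k];
        G[3 * j + k] -= f * d[k];
      }
    }
  }

  for (int r = 0; r < angles.nrow(); ++r) {
    int i = angles(r, 0) - 1, j = angles(r, 1) - 1, k = angles(r, 2) - 1;
    double u[3] = {X[3 * i] - X[3 * j], X[3 * i + 1] - X[3 * j + 1],
                   X[3 * i + 2] - X[3 * j + 2]};
    double v[3] = {X[3 * k] - X[3 * j], X[3 * k + 1] - X[3 * j + 1],
                   X[3 * k + 2] - X[3 * j + 2]};
    double nu = norm3(u), nv = norm3(v);
    double ct = dot3(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - th0[r];
    e_angle += ka * dth * dth;
    if (want_grad) {
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      double pref = -2 * ka * dth / st;
      for (int m = 0; m < 3; ++m) {
        double dui = (v[m] / (nu * nv)) - ct * u[m] / (nu * nu);
        double dvk = (u[m] / (nu * nv)) - ct * v[m] / (nv * nv);
        G[3 * i + m] += pref * dui;
        G[3 * k + m] += pref * dvk;
        G[3 * j + m] -= pref * (dui + dvk);
      }
    }
  }

  for (int r = 0; r < tors.nrow(); ++r) {
    int i = tors(r, 0) - 1, j = tors(r, 1) - 1, k = tors(r, 2) - 1,
        l = tors(r, 3) - 1;
    double b1[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                    X[3 * j + 2] - X[3 * i + 2]};
    double b2[3] = {X[3 * k] - X[3 * j], X[3 * k + 1] - X[3 * j + 1],
                    X[3 * k + 2] - X[3 * j + 2]};
    double b3[3] = {X[3 * l] - X[3 * k], X[3 * l + 1] - X[3 * k + 1],
                    X[3 * l + 2] - X[3 * k + 2]};
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double nb2 = norm3(b2);
    double cx[3];
    cross3(n1, n2, cx);
    double ph = std::atan2(dot3(cx, b2) / nb2, dot3(n1, n2));
    double dph = ph - ph0[r];
    while (dph > M_PI) dph -= 2 * M_PI;
    while (dph < -M_PI) dph += 2 * M_PI;
    e_tors += kt * dph * dph;
    if (want_grad) {
      // standard analytic torsion gradient
      double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (n1sq < 1e-12 || n2sq < 1e-12) continue;
      double pref = 2 * kt * dph;
      double gi[3], gl[3];
      for (int m = 0; m < 3; ++m) {
        gi[m] = -pref * nb2 / n1sq * n1[m];
        gl[m] = pref * nb2 / n2sq * n2[m];
      }
      double d12 = dot3(b1, b2), d32 = dot3(b3, b2);
      for (int m = 0; m < 3; ++m) {
        double gj = (d12 / (nb2 * nb2) - 1.0) * gi[m] -
                    d32 / (nb2 * nb2) * gl[m];
        double gk = (d32 / (nb2 * nb2) - 1.0) * gl[m] -
                    d12 / (nb2 * nb2) * gi[m];
        G[3 * i + m] += gi[m];
        G[3 * j + m] += gj;
        G[3 * k + m] += gk;
        G[3 * l + m] += gl[m];
      }
    }
  }

  // Verlet pair list with displacement-triggered rebuild; exclusions are
  // applied at rebuild time. Pairs beyond rmin contribute exactly zero, so
  // the cached list changes no energy value, only the iteration cost.
  static std::vector<int> vl_pairs;
  static std::vector<double> vl_xref;
  static int vl_n = -1;
  static double vl_rlist = 0;
  const double skin = 0.8;
  double rlist = rmin + skin;
  bool rebuild = (vl_n != n) || (vl_rlist != rlist);
  if (!rebuild) {
    double maxd2 = 0;
    for (int i = 0; i < 3 * n; ++i) {
      double d = X[i] - vl_xref[i];
      maxd2 = std::max(maxd2, d * d);
    }
    // conservative: any single coordinate moving skin/2 triggers rebuild
    if (maxd2 > (skin * skin) / 16.0) rebuild = true;
  }
  if (rebuild) {
    vl_pairs.clear();
    vl_n = n;
    vl_rlist = rlist;
    vl_xref = X;
    const double* EK = excl_keys.begin();
    int nek = excl_keys.size();
    CellList cl;
    cl.build(X, n, rlist);
    double rl2 = rlist * rlist;
    for (int i = 0; i < n; ++i) {
      const double* pi = &X[3 * i];
      int cx = std::min(cl.dim[0] - 1,
                        std::max(0, (int)((pi[0] - cl.lo[0]) / cl.cell)));
      int cy = std::min(cl.dim[1] - 1,
                        std::max(0, (int)((pi[1] - cl.lo[1]) / cl.cell)));
      int cz = std::min(cl.dim[2] - 1,
                        std::max(0, (int)((pi[2] - cl.lo[2]) / cl.cell)));
      for (int dx = -1; dx <= 1; ++dx) {
        if (cx + dx < 0 || cx + dx >= cl.dim[0]) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          if (cy + dy < 0 || cy + dy >= cl.dim[1]) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (cz + dz < 0 || cz + dz >= cl.dim[2]) continue;
            int j = cl.head[((cx + dx) * cl.dim[1] + cy + dy) * cl.dim[2] +
                            cz + dz];
            for (; j >= 0; j = cl.nxt[j]) {
              if (j <= i) continue;
              double d[3] = {pi[0] - X[3 * j], pi[1] - X[3 * j + 1],
                             pi[2] - X[3 * j + 2]};
              if (dot3(d, d) >= rl2) continue;
              double key = (double)i * 100000.0 + j;
              if (std::binary_search(EK, EK + nek, key)) continue;
              vl_pairs.push_back(i);
              vl_pairs.push_back(j);
            }
          }
        }
      }
    }
  }
  double r2min = rmin * rmin;
  for (size_t t = 0; t < vl_pairs.size(); t += 2) {
    int i = vl_pairs[t], j = vl_pairs[t + 1];
    double d[3] = {X[3 * i] - X[3 * j], X[3 * i + 1] - X[3 * j + 1],
                   X[3 * i + 2] - X[3 * j + 2]};
    double r2 = dot3(d, d);
    if (r2 >= r2min || r2 < 1e-12) continue;
    double r = std::sqrt(r2);
    double s = rmin / r;
    double s6 = s * s * s; s6 *= s6;
    double w = s6 - 1.0;
    e_rep += eps * w * w;
    if (want_grad) {
      double dEdr = eps * 2 * w * (-6.0 * s6 / r);
      for (int k = 0; k < 3; ++k) {
        G[3 * i + k] += dEdr * d[k] / r;
        G[3 * j + k] -= dEdr * d[k] / r;
      }
    }
  }

  List out = List::create(
    _["energy"] = e_bond + e_angle + e_tors + e_rep,
    _["bond"] = e_bond, _["angle"] = e_angle,
    _["torsion"] = e_tors, _["repulsion"] = e_rep);
  if (want_grad) out["grad"] = NumericVector(G.begin(), G.end());
  return out;
}

// ---- nonphysical geometry detection --------------------------------------

static double seg_seg_dist(const double* p1, const double* p2,
                           const double* q1, const double* q2) {
  double d1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double d2[3] = {q2[0] - q1[0], q2[1] - q1[1], q2[2] - q1[2]};
  double r[3] = {p1[0] - q1[0], p1[1] - q1[1], p1[2] - q1[2]};
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double c = dot3(d1, r), b = dot3(d1, d2);
  double denom = a * e - b * b;
  double s = (denom > 1e-12) ? (b * f - c * e) / denom : 0.0;
  s = std::max(0.0, std::min(1.0, s));
  double t = (e > 1e-12) ? (b * s + f) / e : 0.0;
  if (t < 0) { t = 0; s = std::max(0.0, std::min(1.0, -c / a)); }
  else if (t > 1) { t = 1; s = std::max(0.0, std::min(1.0, (b - c) / a)); }
  double cp[3], cq[3];
  for (int k = 0; k < 3; ++k) {
    cp[k] = p1[k] + s * d1[k];
    cq[k] = q1[k] + t * d2[k];
  }
  double d[3] = {cp[0] - cq[0], cp[1] - cq[1], cp[2] - cq[2]};
  return norm3(d);
}

static bool seg_tri_intersect(const double* p, const double* q,
                              const double* a, const double* b,
                              const double* c) {
  // Moller-Trumbore for segment pq against triangle abc
  double dir[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double h[3];
  cross3(dir, e2, h);
  double det = dot3(e1, h);
  if (std::fabs(det) < 1e-12) return false;
  double inv = 1.0 / det;
  double s[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double u = inv * dot3(s, h);
  if (u < 0 || u > 1) return false;
  double qv[3];
  cross3(s, e1, qv);
  double v = inv * dot3(dir, qv);
  if (v < 0 || u + v > 1) return false;
  double t = inv * dot3(e2, qv);
  return (t >= 0 && t <= 1);
}

// overlapping bond segments (< tol apart, sharing no atom and not
// connected through one) and bonds piercing the fan-triangulated surface
// of another residue's ring
// [[Rcpp::export(name = ".detect_nonphysical")]]
List detect_nonphysical_cpp(NumericMatrix coords, IntegerMatrix bonds,
                            IntegerMatrix ring_idx, IntegerVector res_of,
                            double overlap_tol) {
  int nb = bonds.nrow();
  int n = coords.nrow();
  std::vector<double> X(3 * n);
  for (int i = 0; i < n; ++i) {
    X[3 * i] = coords(i, 0); X[3 * i + 1] = coords(i, 1);
    X[3 * i + 2] = coords(i, 2);
  }
  // adjacency for the "non-adjacent segments" rule
  std::vector<std::vector<int> > adj(n);
  for (int r = 0; r < nb; ++r) {
    adj[bonds(r, 0) - 1].push_back(bonds(r, 1) - 1);
    adj[bonds(r, 1) - 1].push_back(bonds(r, 0) - 1);
  }
  std::vector<int> oi, oj;
  for (int r = 0; r < nb; ++r) {
    int a1 = bonds(r, 0) - 1, a2 = bonds(r, 1) - 1;
    for (int s = r + 1; s < nb; ++s) {
      int b1 = bonds(s, 0) - 1, b2 = bonds(s, 1) - 1;
      if (a1 == b1 || a1 == b2 || a2 == b1 || a2 == b2) continue;
      bool touching = false;
      for (size_t t = 0; t < adj[a1].size() && !touching; ++t) {
        if (adj[a1][t] == b1 || adj[a1][t] == b2) touching = true;
      }
      for (size_t t = 0; t < adj[a2].size() && !touching; ++t) {
        if (adj[a2][t] == b1 || adj[a2][t] == b2) touching = true;
      }
      if (touching) continue;
      // cheap reject: midpoint distance
      double mx = 0.5 * (X[3 * a1] + X[3 * a2]) - 0.5 * (X[3 * b1] + X[3 * b2]);
      double my = 0.5 * (X[3 * a1 + 1] + X[3 * a2 + 1]) -
                  0.5 * (X[3 * b1 + 1] + X[3 * b2 + 1]);
      double mz = 0.5 * (X[3 * a1 + 2] + X[3 * a2 + 2]) -
                  0.5 * (X[3 * b1 + 2] + X[3 * b2 + 2]);
      if (mx * mx + my * my + mz * mz > 16.0) continue;
      double d = seg_seg_dist(&X[3 * a1], &X[3 * a2], &X[3 * b1], &X[3 * b2]);
      if (d < overlap_tol) {
        oi.push_back(r + 1);
        oj.push_back(s + 1);
      }
    }
  }
  // ring piercing: fan triangulation about the ring centroid
  std::vector<int> pb, pr;
  int nres = ring_idx.nrow();
  for (int ri = 0; ri < nres; ++ri) {
    double cen[3] = {0, 0, 0};
    for (int k = 0; k < 6; ++k) {
      int ai = ring_idx(ri, k) - 1;
      for (int m = 0; m < 3; ++m) cen[m] += X[3 * ai + m] / 6.0;
    }
    for (int r = 0; r < nb; ++r) {
      int a1 = bonds(r, 0) - 1, a2 = bonds(r, 1) - 1;
      if (res_of[a1] - 1 == ri || res_of[a2] - 1 == ri) continue;
      // cheap reject
      double mx = 0.5 * (X[3 * a1] + X[3 * a2]) - cen[0];
      double my = 0.5 * (X[3 * a1 + 1] + X[3 * a2 + 1]) - cen[1];
      double mz = 0.5 * (X[3 * a1 + 2] + X[3 * a2 + 2]) - cen[2];
      if (mx * mx + my * my + mz * mz > 25.0) continue;
      for (int k = 0; k < 6; ++k) {
        int v1 = ring_idx(ri, k) - 1;
        int v2 = ring_idx(ri, (k + 1) % 6) - 1;
        if (seg_tri_intersect(&X[3 * a1], &X[3 * a2], cen,
                              &X[3 * v1], &X[3 * v2])) {
          pb.push_back(r + 1);
          pr.push_back(ri + 1);
          break;
        }
      }
    }
  }
  return List::create(
    _["overlap_bonds"] = cbind(IntegerVector(oi.begin(), oi.end()),
                               IntegerVector(oj.begin(), oj.end())),
    _["pierce_bond"] = IntegerVector(pb.begin(), pb.end()),
    _["pierce_residue"] = IntegerVector(pr.begin(), pr.end()));
}
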