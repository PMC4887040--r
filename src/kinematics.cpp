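// Kinematic chain kernel: NeRF-style internal->Cartesian placement, closure
// objective + numerical gradient, and an extended-CCD baseline optimizer.
//
// A chain is a Z-matrix: row i places one atom from three previously placed
// atoms (a, b, c) with a bond length |d-c|, a bond angle (b,c,d) and a
// torsion dihedral (a,b,c,d).  Indices are 1-based into the combined
// coordinate array [fixed anchors; placed atoms].  Rows must be ordered so
// that every reference points to an anchor or an earlier row, and so that
// rotating the torsion of row i rigidly moves all atoms of rows >= i (the
// loop builder guarantees this path ordering).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = 3.14159265358979323846 / 180.0;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline Vec3 vadd(const Vec3& a, const Vec3& b) {
  Vec3 r = {a.x + b.x, a.y + b.y, a.z + b.z};
  return r;
}
static inline Vec3 vscale(const Vec3& a, double s) {
  Vec3 r = {a.x * s, a.y * s, a.z * s};
  return r;
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return r;
}
static inline double vnorm(const Vec3& a) { return std::sqrt(vdot(a, a)); }
static inline Vec3 vunit(const Vec3& a) {
  double n = vnorm(a);
  return vscale(a, n > 0 ? 1.0 / n : 0.0);
}

// Place atom d from reference atoms a, b, c and internal coordinates.
static inline Vec3 nerf_place(const Vec3& a, const Vec3& b, const Vec3& c,
                              double len, double ang_deg, double tor_deg) {
  double ang = ang_deg * DEG, tor = tor_deg * DEG;
  Vec3 bc = vunit(vsub(c, b));
  Vec3 n = vunit(vcross(vsub(b, a), bc));
  Vec3 m = vcross(n, bc);
  // local displacement in frame (bc, m, n)
  double d1 = -len * std::cos(ang);
  double d2 = len * std::sin(ang) * std::cos(tor);
  double d3 = len * std::sin(ang) * std::sin(tor);
  Vec3 d = vadd(c, vadd(vscale(bc, d1), vadd(vscale(m, d2), vscale(n, d3))));
  return d;
}

// Evaluate the whole chain into `out` (pre-sized nf + n rows).
static void place_chain(const NumericMatrix& fixed, const NumericMatrix& zmat,
                        const NumericVector& dof_row, const NumericVector& dof_par,
                        const NumericVector& dof_val, std::vector<Vec3>& out) {
  int nf = fixed.nrow(), n = zmat.nrow();
  for (int i = 0; i < nf; ++i) out[i] = {fixed(i, 0), fixed(i, 1), fixed(i, 2)};
  // copy IC parameters, apply DOF overrides
  std::vector<double> len(n), ang(n), tor(n);
  for (int i = 0; i < n; ++i) {
    len[i] = zmat(i, 3);
    ang[i] = zmat(i, 4);
    tor[i] = zmat(i, 5);
  }
  for (int k = 0; k < dof_row.size(); ++k) {
    int r = (int)dof_row[k] - 1;
    if ((int)dof_par[k] == 2) ang[r] = dof_val[k]; else tor[r] = dof_val[k];
  }
  for (int i = 0; i < n; ++i) {
    const Vec3& a = out[(int)zmat(i, 0) - 1];
    const Vec3& b = out[(int)zmat(i, 1) - 1];
    const Vec3& c = out[(int)zmat(i, 2) - 1];
    out[nf + i] = nerf_place(a, b, c, len[i], ang[i], tor[i]);
  }
}

static double chain_objective(const std::vector<Vec3>& coords,
                              const NumericVector& target_row,
                              const NumericMatrix& target_xyz,
                              const NumericVector& target_w) {
  double f = 0.0;
  for (int k = 0; k < target_row.size(); ++k) {
    const Vec3& p = coords[(int)target_row[k] - 1];
    Vec3 q = {target_xyz(k, 0), target_xyz(k, 1), target_xyz(k, 2)};
    Vec3 d = vsub(p, q);
    f += target_w[k] * vdot(d, d);
  }
  return f;
}

// [[Rcpp::export]]
NumericMatrix chain_place_cpp(NumericMatrix fixed, NumericMatrix zmat,
                              NumericVector dof_row, NumericVector dof_par,
                              NumericVector dof_val) {
  int nf = fixed.nrow(), n = zmat.nrow();
  std::vector<Vec3> coords(nf + n);
  place_chain(fixed, zmat, dof_row, dof_par, dof_val, coords);
  NumericMatrix out(nf + n, 3);
  for (int i = 0; i < nf + n; ++i) {
    out(i, 0) = coords[i].x;
    out(i, 1) = coords[i].y;
    out(i, 2) = coords[i].z;
  }
  return out;
}

// [[Rcpp::export]]
double chain_obj_cpp(NumericMatrix fixed, NumericMatrix zmat,
                     NumericVector dof_row, NumericVector dof_par,
                     NumericVector dof_val, NumericVector target_row,
                     NumericMatrix target_xyz, NumericVector target_w) {
  std::vector<Vec3> coords(fixed.nrow() + zmat.nrow());
  place_chain(fixed, zmat, dof_row, dof_par, dof_val, coords);
  return chain_objective(coords, target_row, target_xyz, target_w);
}

// Central-difference gradient of the closure objective wrt the DOF vector.
// [[Rcpp::export]]
NumericVector chain_grad_cpp(NumericMatrix fixed, NumericMatrix zmat,
                             NumericVector dof_row, NumericVector dof_par,
                             NumericVector dof_val, NumericVector target_row,
                             NumericMatrix target_xyz, NumericVector target_w,
                             double h = 1e-4) {
  int nd = dof_val.size();
  NumericVector g(nd);
  NumericVector v = clone(dof_val);
  std::vector<Vec3> coords(fixed.nrow() + zmat.nrow());
  for (int k = 0; k < nd; ++k) {
    double v0 = v[k];
    v[k] = v0 + h;
    place_chain(fixed, zmat, dof_row, dof_par, v, coords);
    double fp = chain_objective(coords, target_row, target_xyz, target_w);
    v[k] = v0 - h;
    place_chain(fixed, zmat, dof_row, dof_par, v, coords);
    double fm = chain_objective(coords, target_row, target_xyz, target_w);
    v[k] = v0;
    g[k] = (fp - fm) / (2.0 * h);
  }
  return g;
}

static inline double wrap180(double x) {
  while (x > 180.0) x -= 360.0;
  while (x <= -180.0) x += 360.0;
  return x;
}

// Extended CCD: torsion DOFs get the analytic one-axis update minimizing the
// weighted multi-point target objective; bond-angle DOFs are relaxed by a
// bounded 1-D scan with parabolic refinement.  Sweeps until the objective
// improvement stalls or max_sweeps is hit.
// [[Rcpp::export]]
List ccd_close_cpp(NumericMatrix fixed, NumericMatrix zmat,
                   NumericVector dof_row, NumericVector dof_par,
                   NumericVector dof_init, NumericVector lower,
                   NumericVector upper, NumericVector target_row,
                   NumericMatrix target_xyz, NumericVector target_w,
                   int max_sweeps = 200, double ftol = 1e-10,
                   int angle_every = 1) {
  int nf = fixed.nrow(), n = zmat.nrow(), nd = dof_init.size();
  NumericVector val = clone(dof_init);
  std::vector<Vec3> coords(nf + n);
  place_chain(fixed, zmat, dof_row, dof_par, val, coords);
  double f = chain_objective(coords, target_row, target_xyz, target_w);
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double f_start = f;
    for (int k = 0; k < nd; ++k) {
      int r = (int)dof_row[k] - 1;
      if ((int)dof_par[k] == 3) {
        // analytic torsion update: rotation about axis b->c of row r moves
        // all atoms of rows >= r rigidly (builder ordering guarantee)
        place_chain(fixed, zmat, dof_row, dof_par, val, coords);
        Vec3 b = coords[(int)zmat(r, 1) - 1];
        Vec3 c = coords[(int)zmat(r, 2) - 1];
        Vec3 u = vunit(vsub(c, b));
        double A = 0.0, B = 0.0;
        bool any = false;
        for (int t = 0; t < target_row.size(); ++t) {
          int ti = (int)target_row[t] - 1;
          if (ti < nf + r) continue;  // target not downstream of this torsion
          any = true;
          Vec3 p = coords[ti];
          Vec3 q = {target_xyz(t, 0), target_xyz(t, 1), target_xyz(t, 2)};
          Vec3 pc = vsub(p, c);
          Vec3 o = vadd(c, vscale(u, vdot(pc, u)));  // foot on axis
          Vec3 v = vsub(p, o);
          Vec3 d = vsub(q, o);
          A += target_w[t] * vdot(v, d);
          B += target_w[t] * vdot(vcross(u, v), d);
        }
        if (!any) continue;
        double dtheta = std::atan2(B, A) / DEG;
        double cand = wrap180(val[k] + dtheta);
        // respect bounds: evaluate candidate (clamped) and keep if better
        if (cand < lower[k]) cand = lower[k];
        if (cand > upper[k]) cand = upper[k];
        double old = val[k];
        val[k] = cand;
        place_chain(fixed, zmat, dof_row, dof_par, val, coords);
        double fc = chain_objective(coords, target_row, target_xyz, target_w);
        if (fc <= f) f = fc; else val[k] = old;
      } else {
        // bounded scan for an angle DOF (optionally only every n-th sweep:
        // angle ranges are narrow, so relaxing them less often is cheaper)
        if (angle_every > 1 && (sweeps % angle_every) != 0) continue;
        double lo = lower[k], hi = upper[k];
        double best = val[k], fbest = f;
        int ngrid = 13;
        for (int g = 0; g < ngrid; ++g) {
          double cand = lo + (hi - lo) * g / (ngrid - 1.0);
          val[k] = cand;
          place_chain(fixed, zmat, dof_row, dof_par, val, coords);
          double fc = chain_objective(coords, target_row, target_xyz, target_w);
          if (fc < fbest) { fbest = fc; best = cand; }
        }
        // one parabolic refinement step around the best grid point
        double step = (hi - lo) / (ngrid - 1.0);
        if (step > 0) {
          double xm = best, x1 = std::max(lo, best - step), x2 = std::min(hi, best + step);
          val[k] = x1;
          place_chain(fixed, zmat, dof_row, dof_par, val, coords);
          double f1 = chain_objective(coords, target_row, target_xyz, target_w);
          val[k] = x2;
          place_chain(fixed, zmat, dof_row, dof_par, val, coords);
          double f2 = chain_objective(coords, target_row, target_xyz, target_w);
          double denom = (x1 - xm) * (f2 - fbest) - (x2 - xm) * (f1 - fbest);
          if (std::fabs(denom) > 1e-30) {
            double num = (x1 - xm) * (x1 - xm) * (f2 - fbest) -
                         (x2 - xm) * (x2 - xm) * (f1 - fbest);
            double xq = xm + 0.5 * num / denom * (-1.0);
            if (xq >= lo && xq <= hi) {
              val[k] = xq;
              place_chain(fixed, zmat, dof_row, dof_par, val, coords);
              double fq = chain_objective(coords, target_row, target_xyz, target_w);
              if (fq < fbest) { fbest = fq; best = xq; }
            }
          }
        }
        val[k] = best;
        f = fbest;
      }
    }
    if (f_start - f < ftol) break;
  }
  place_chain(fixed, zmat, dof_row, dof_par, val, coords);
  f = chain_objective(coords, target_row, target_xyz, target_w);
  return List::create(_["par"] = val, _["value"] = f, _["sweeps"] = sweeps + 1);
}

// Linear repulsive clash energy between two disjoint atom groups:
//   e(r) = k * max(0, c*(Ri+Rj) - r) / (c*(Ri+Rj)), summed over pairs.
// [[Rcpp::export]]
double repulsion_cpp(NumericMatrix xyz_a, NumericVector rad_a,
                     NumericMatrix xyz_b, NumericVector rad_b,
                     double c_onset, double k_scale) {
  double e = 0.0;
  int na = xyz_a.nrow(), nb = xyz_b.nrow();
  for (int i = 0; i < na; ++i) {
    double xi = xyz_a(i, 0), yi = xyz_a(i, 1), zi = xyz_a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double onset = c_onset * (rad_a[i] + rad_b[j]);
      double dx = xi - xyz_b(j, 0), dy = yi - xyz_b(j, 1), dz = zi - xyz_b(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < onset * onset) {
        double r = std::sqrt(r2);
        e += k_scale * (onset - r) / onset;
      }
    }
  }
  return e;
}

// Smallest heavy-atom cross distance and per-row minimum distances.
// [[Rcpp::export]]
NumericVector row_min_dist_cpp(NumericMatrix xyz_a, NumericMatrix xyz_b) {
  int na = xyz_a.nrow(), nb = xyz_b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = xyz_a(i, 0) - xyz_b(j, 0);
      double dy = xyz_a(i, 1) - xyz_b(j, 1);
      double dz = xyz_a(i, 2) - xyz_b(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
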