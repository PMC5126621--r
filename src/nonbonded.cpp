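// Nonbonded energy core and degree-of-freedom kinematics.
//
// Terms: 12-6 Lennard-Jones (Lorentz-Berthelot combination), Coulomb
// with distance-dependent dielectric eps(r) = 4r, and a directional
// donor-H...acceptor hydrogen-bond well. LJ and Coulomb are tapered to
// zero with a cubic switching function over the last `swidth` Angstrom
// before the cutoff; the H-bond well is tapered over the last 0.4 A of
// its own distance cutoff and vanishes linearly at the angle cutoff,
// so every term is continuous in the coordinates.

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static inline double sw(double r, double cutoff, double w) {
  if (r >= cutoff) return 0.0;
  if (r <= cutoff - w) return 1.0;
  double t = (cutoff - r) / w;
  return t * t * (3.0 - 2.0 * t);
}

struct EnergyCtx {
  NumericMatrix coords;
  NumericVector q, eps, sig;
  IntegerVector don, acc;
  std::vector<char> excl;  // flat n*n lookup (small systems)
  std::unordered_set<long long> excl_set;  // fallback for large n
  bool flat;
  double cutoff, swidth, kcoul, hb_dist, hb_angle, hb_well;
  IntegerVector active;
  int active_mode;  // 0 all pairs, 1 pairs touching the set, 2 cross only
};

static inline bool excluded(const EnergyCtx &ctx, int i, int j) {
  long long n = ctx.coords.nrow();
  if (ctx.flat) return ctx.excl[(size_t)i * n + j] != 0;
  long long key = (i < j) ? (long long)i * n + j : (long long)j * n + i;
  return ctx.excl_set.count(key) > 0;
}

static void nb_terms(const EnergyCtx &ctx, double &lj, double &coul,
                     double &hb) {
  int n = ctx.coords.nrow();
  const double cut2 = ctx.cutoff * ctx.cutoff;
  lj = 0.0; coul = 0.0; hb = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double xi = ctx.coords(i, 0), yi = ctx.coords(i, 1),
           zi = ctx.coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      if (ctx.active_mode == 1 && !ctx.active[i] && !ctx.active[j]) continue;
      if (ctx.active_mode == 2 && ctx.active[i] == ctx.active[j]) continue;
      double dx = ctx.coords(j, 0) - xi, dy = ctx.coords(j, 1) - yi,
             dz = ctx.coords(j, 2) - zi;
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      if (excluded(ctx, i, j)) continue;
      if (r2 < 1e-12) stop("overlapping atoms (r = 0) in nonbonded sum");
      double r = std::sqrt(r2);
      double s = sw(r, ctx.cutoff, ctx.swidth);
      double sg = 0.5 * (ctx.sig[i] + ctx.sig[j]);
      double ep = std::sqrt(ctx.eps[i] * ctx.eps[j]);
      double sr2 = sg * sg / r2;
      double sr6 = sr2 * sr2 * sr2;
      lj += s * 4.0 * ep * (sr6 * sr6 - sr6);
      coul += s * ctx.kcoul * ctx.q[i] * ctx.q[j] / (4.0 * r2);
    }
  }
  // directional hydrogen bonds: donor D-H ... acceptor A
  for (int h = 0; h < n; ++h) {
    int D = ctx.don[h] - 1;
    if (D < 0) continue;
    for (int a = 0; a < n; ++a) {
      if (!ctx.acc[a] || a == D || a == h) continue;
      if (ctx.active_mode == 1 && !ctx.active[D] && !ctx.active[a] &&
          !ctx.active[h]) continue;
      if (ctx.active_mode == 2 && ctx.active[D] == ctx.active[a]) continue;
      if (excluded(ctx, D, a)) continue;
      double dx = ctx.coords(a, 0) - ctx.coords(D, 0),
             dy = ctx.coords(a, 1) - ctx.coords(D, 1),
             dz = ctx.coords(a, 2) - ctx.coords(D, 2);
      double dDA = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dDA >= ctx.hb_dist || dDA < 1e-6) continue;
      // angle D-H-A at the hydrogen
      double ux = ctx.coords(D, 0) - ctx.coords(h, 0),
             uy = ctx.coords(D, 1) - ctx.coords(h, 1),
             uz = ctx.coords(D, 2) - ctx.coords(h, 2);
      double vx = ctx.coords(a, 0) - ctx.coords(h, 0),
             vy = ctx.coords(a, 1) - ctx.coords(h, 1),
             vz = ctx.coords(a, 2) - ctx.coords(h, 2);
      double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (nu < 1e-6 || nv < 1e-6) continue;
      double ca = (ux * vx + uy * vy + uz * vz) / (nu * nv);
      if (ca > 1.0) ca = 1.0; if (ca < -1.0) ca = -1.0;
      double ang = std::acos(ca) * 180.0 / M_PI;
      if (ang < ctx.hb_angle) continue;
      double fang = (ang - ctx.hb_angle) / (180.0 - ctx.hb_angle);
      hb -= ctx.hb_well * sw(dDA, ctx.hb_dist, 0.4) * fang;
    }
  }
}

static EnergyCtx make_ctx(NumericMatrix coords, NumericVector q,
                          NumericVector eps, NumericVector sig,
                          IntegerVector don, IntegerVector acc,
                          IntegerVector excl_i, IntegerVector excl_j,
                          List pars, IntegerVector active,
                          int active_mode) {
  EnergyCtx ctx{coords, q, eps, sig, don, acc, {}, {}, false,
                as<double>(pars["nonbonded_cutoff"]),
                as<double>(pars["switch_width"]),
                as<double>(pars["coulomb_constant"]),
                as<double>(pars["hbond_distance_cutoff"]),
                as<double>(pars["hbond_angle_cutoff"]),
                as<double>(pars["hbond_well_depth"]),
                active, active.size() > 0 ? active_mode : 0};
  long long n = coords.nrow();
  ctx.flat = n <= 2000;
  if (ctx.flat) {
    ctx.excl.assign((size_t)n * n, 0);
    for (int k = 0; k < excl_i.size(); ++k) {
      long long i = excl_i[k] - 1, j = excl_j[k] - 1;
      ctx.excl[(size_t)i * n + j] = 1;
      ctx.excl[(size_t)j * n + i] = 1;
    }
  } else {
    ctx.excl_set.reserve(excl_i.size() * 2);
    for (int k = 0; k < excl_i.size(); ++k) {
      long long i = excl_i[k] - 1, j = excl_j[k] - 1;
      ctx.excl_set.insert((i < j) ? i * n + j : j * n + i);
    }
  }
  return ctx;
}

// [[Rcpp::export]]
NumericVector nb_terms_cpp(NumericMatrix coords, NumericVector q,
                           NumericVector eps, NumericVector sig,
                           IntegerVector don, IntegerVector acc,
                           IntegerVector excl_i, IntegerVector excl_j,
                           List pars, IntegerVector active,
                           int active_mode = 1) {
  EnergyCtx ctx = make_ctx(coords, q, eps, sig, don, acc,
                           excl_i, excl_j, pars, active, active_mode);
  double lj, coul, hb;
  nb_terms(ctx, lj, coul, hb);
  return NumericVector::create(_["lj"] = lj, _["coulomb"] = coul,
                               _["hbond"] = hb);
}

static double torsion_sum(const NumericMatrix &coords,
                          const IntegerMatrix &quads, double k) {
  double e = 0.0;
  for (int t = 0; t < quads.nrow(); ++t) {
    int a = quads(t, 0) - 1, b = quads(t, 1) - 1, c = quads(t, 2) - 1,
        d = quads(t, 3) - 1;
    double b1[3], b2[3], b3[3];
    for (int m = 0; m < 3; ++m) {
      b1[m] = coords(b, m) - coords(a, m);
      b2[m] = coords(c, m) - coords(b, m);
      b3[m] = coords(d, m) - coords(c, m);
    }
    double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                    b1[2] * b2[0] - b1[0] * b2[2],
                    b1[0] * b2[1] - b1[1] * b2[0]};
    double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                    b2[2] * b3[0] - b2[0] * b3[2],
                    b2[0] * b3[1] - b2[1] * b3[0]};
    double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    if (nb2 < 1e-9) continue;
    double m1[3] = {n1[1] * b2[2] - n1[2] * b2[1],
                    n1[2] * b2[0] - n1[0] * b2[2],
                    n1[0] * b2[1] - n1[1] * b2[0]};
    double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double y = (m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2]) / nb2;
    double phi = std::atan2(y, x);
    e += k * (1.0 + std::cos(3.0 * phi));
  }
  return e;
}

// [[Rcpp::export]]
double torsion_energy_cpp(NumericMatrix coords, IntegerMatrix quads,
                          double k) {
  return torsion_sum(coords, quads, k);
}

static void rotate_set(NumericMatrix &m, const IntegerVector &idx,
                       const double *origin, const double *axis,
                       double angle_deg) {
  double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                         axis[2] * axis[2]);
  if (nrm < 1e-12 || std::fabs(angle_deg) < 1e-15) return;
  double k0 = axis[0] / nrm, k1 = axis[1] / nrm, k2 = axis[2] / nrm;
  double th = angle_deg * M_PI / 180.0, ct = std::cos(th),
         st = std::sin(th);
  for (int ii = 0; ii < idx.size(); ++ii) {
    int i = idx[ii] - 1;
    double p0 = m(i, 0) - origin[0], p1 = m(i, 1) - origin[1],
           p2 = m(i, 2) - origin[2];
    double c0 = k1 * p2 - k2 * p1, c1 = k2 * p0 - k0 * p2,
           c2 = k0 * p1 - k1 * p0;
    double kd = k0 * p0 + k1 * p1 + k2 * p2;
    m(i, 0) = origin[0] + p0 * ct + c0 * st + k0 * kd * (1 - ct);
    m(i, 1) = origin[1] + p1 * ct + c1 * st + k1 * kd * (1 - ct);
    m(i, 2) = origin[2] + p2 * ct + c2 * st + k2 * kd * (1 - ct);
  }
}

struct DofOp {
  int type, a1, a2;
  std::vector<int> moving;  // 0-based
};

static std::vector<DofOp> decode_ops(List ops) {
  std::vector<DofOp> out;
  out.reserve(ops.size());
  for (int o = 0; o < ops.size(); ++o) {
    List op = ops[o];
    DofOp d;
    d.type = as<int>(op["type"]);
    d.a1 = d.a2 = -1;
    if (d.type == 0) {
      d.a1 = as<int>(op["a1"]) - 1;
      d.a2 = as<int>(op["a2"]) - 1;
    }
    IntegerVector mv = op["moving"];
    d.moving.assign(mv.begin(), mv.end());
    for (size_t i = 0; i < d.moving.size(); ++i) d.moving[i] -= 1;
    out.push_back(d);
  }
  return out;
}

static void rotate_idx(NumericMatrix &m, const std::vector<int> &idx,
                       const double *origin, const double *axis,
                       double angle_deg) {
  double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                         axis[2] * axis[2]);
  if (nrm < 1e-12 || std::fabs(angle_deg) < 1e-15) return;
  double k0 = axis[0] / nrm, k1 = axis[1] / nrm, k2 = axis[2] / nrm;
  double th = angle_deg * M_PI / 180.0, ct = std::cos(th),
         st = std::sin(th);
  for (size_t ii = 0; ii < idx.size(); ++ii) {
    int i = idx[ii];
    double p0 = m(i, 0) - origin[0], p1 = m(i, 1) - origin[1],
           p2 = m(i, 2) - origin[2];
    double c0 = k1 * p2 - k2 * p1, c1 = k2 * p0 - k0 * p2,
           c2 = k0 * p1 - k1 * p0;
    double kd = k0 * p0 + k1 * p1 + k2 * p2;
    m(i, 0) = origin[0] + p0 * ct + c0 * st + k0 * kd * (1 - ct);
    m(i, 1) = origin[1] + p1 * ct + c1 * st + k1 * kd * (1 - ct);
    m(i, 2) = origin[2] + p2 * ct + c2 * st + k2 * kd * (1 - ct);
  }
}

static NumericMatrix apply_decoded(const NumericMatrix &coords,
                                   const std::vector<DofOp> &ops,
                                   const NumericVector &x) {
  NumericMatrix m = clone(coords);
  int k = 0;
  for (size_t o = 0; o < ops.size(); ++o) {
    const DofOp &op = ops[o];
    if (op.type == 0) {
      double origin[3] = {m(op.a1, 0), m(op.a1, 1), m(op.a1, 2)};
      double axis[3] = {m(op.a2, 0) - m(op.a1, 0),
                        m(op.a2, 1) - m(op.a1, 1),
                        m(op.a2, 2) - m(op.a1, 2)};
      rotate_idx(m, op.moving, origin, axis, x[k]);
      k += 1;
    } else {
      double cen[3] = {0, 0, 0};
      for (size_t ii = 0; ii < op.moving.size(); ++ii)
        for (int d = 0; d < 3; ++d) cen[d] += m(op.moving[ii], d);
      for (int d = 0; d < 3; ++d) cen[d] /= op.moving.size();
      double axis[3] = {x[k], x[k + 1], x[k + 2]};
      double ang = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                             axis[2] * axis[2]);
      if (ang > 1e-12) rotate_idx(m, op.moving, cen, axis, ang);
      for (size_t ii = 0; ii < op.moving.size(); ++ii) {
        int i = op.moving[ii];
        m(i, 0) += x[k + 3]; m(i, 1) += x[k + 4]; m(i, 2) += x[k + 5];
      }
      k += 6;
    }
  }
  return m;
}

// Apply a DOF vector to base coordinates. Ops are applied in order:
// type 0 (dihedral): rotate `moving` about the a1->a2 axis by x[k]
// degrees (1 parameter); type 1 (rigid body): rotate `moving` about its
// centroid by the rotation vector x[k..k+2] (degrees) and translate by
// x[k+3..k+5] (Angstrom; 6 parameters).
// [[Rcpp::export]]
NumericMatrix apply_ops_cpp(NumericMatrix coords, List ops,
                            NumericVector x) {
  return apply_decoded(coords, decode_ops(ops), x);
}

// Harmonic positional tethers: k * |x_i - ref_i|^2 summed over the
// tethered atoms (used by synthetic fixtures to emulate the rigidity
// the surrounding protein core would provide).
// [[Rcpp::export]]
double tether_energy_cpp(NumericMatrix coords, IntegerVector rows,
                         NumericMatrix ref, double k) {
  double e = 0.0;
  for (int t = 0; t < rows.size(); ++t) {
    int i = rows[t] - 1;
    double dx = coords(i, 0) - ref(t, 0), dy = coords(i, 1) - ref(t, 1),
           dz = coords(i, 2) - ref(t, 2);
    e += k * (dx * dx + dy * dy + dz * dz);
  }
  return e;
}

static double dof_total(NumericMatrix coords,
                        const std::vector<DofOp> &ops, NumericVector x,
                        EnergyCtx &ctx, const IntegerMatrix &quads,
                        double tk, NumericVector w,
                        const IntegerVector &tether_rows,
                        const NumericMatrix &tether_ref, double tether_k) {
  NumericMatrix m = apply_decoded(coords, ops, x);
  ctx.coords = m;
  double lj, coul, hb;
  nb_terms(ctx, lj, coul, hb);
  double tors = torsion_sum(m, quads, tk);
  double rest = tether_energy_cpp(m, tether_rows, tether_ref, tether_k);
  return w[0] * lj + w[1] * coul + w[2] * hb + w[3] * tors + rest;
}

// Objective and central-difference gradient in one pass; the energy
// context (exclusion set etc.) is built once and reused for all
// 2n + 1 evaluations.
// [[Rcpp::export]]
List dof_energy_grad_cpp(NumericMatrix coords, List ops, NumericVector x,
                         NumericVector q, NumericVector eps,
                         NumericVector sig, IntegerVector don,
                         IntegerVector acc, IntegerVector excl_i,
                         IntegerVector excl_j, IntegerMatrix quads,
                         List pars, NumericVector w,
                         IntegerVector tether_rows,
                         NumericMatrix tether_ref, double tether_k,
                         double h) {
  EnergyCtx ctx = make_ctx(coords, q, eps, sig, don, acc, excl_i, excl_j,
                           pars, IntegerVector(0), 0);
  double tk = as<double>(pars["torsion_k"]);
  std::vector<DofOp> dops = decode_ops(ops);
  double f0 = dof_total(coords, dops, x, ctx, quads, tk, w, tether_rows,
                        tether_ref, tether_k);
  int n = x.size();
  NumericVector g(n);
  NumericVector xp = clone(x);
  for (int i = 0; i < n; ++i) {
    xp[i] = x[i] + h;
    double fp = dof_total(coords, dops, xp, ctx, quads, tk, w, tether_rows,
                          tether_ref, tether_k);
    xp[i] = x[i] - h;
    double fm = dof_total(coords, dops, xp, ctx, quads, tk, w, tether_rows,
                          tether_ref, tether_k);
    xp[i] = x[i];
    g[i] = (fp - fm) / (2.0 * h);
  }
  return List::create(_["value"] = f0, _["grad"] = g);
}

// Objective for the minimiser: apply DOF, return the weighted total
// energy (and optionally the moved coordinates).
// [[Rcpp::export]]
List dof_energy_cpp(NumericMatrix coords, List ops, NumericVector x,
                    NumericVector q, NumericVector eps, NumericVector sig,
                    IntegerVector don, IntegerVector acc,
                    IntegerVector excl_i, IntegerVector excl_j,
                    IntegerMatrix quads, List pars, NumericVector w,
                    IntegerVector tether_rows, NumericMatrix tether_ref,
                    double tether_k, bool return_coords) {
  NumericMatrix m = apply_ops_cpp(coords, ops, x);
  EnergyCtx ctx = make_ctx(m, q, eps, sig, don, acc, excl_i, excl_j,
                           pars, IntegerVector(0), 0);
  double lj, coul, hb;
  nb_terms(ctx, lj, coul, hb);
  double tors = torsion_sum(m, quads, as<double>(pars["torsion_k"]));
  double rest = tether_energy_cpp(m, tether_rows, tether_ref, tether_k);
  double total = w[0] * lj + w[1] * coul + w[2] * hb + w[3] * tors + rest;
  if (return_coords)
    return List::create(_["total"] = total, _["lj"] = lj,
                        _["coulomb"] = coul, _["hbond"] = hb,
                        _["torsion"] = tors, _["restraint"] = rest,
                        _["coords"] = m);
  return List::create(_["total"] = total);
}
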