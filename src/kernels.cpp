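// Simulation kernels: pair potentials, system forces, SARW growth,
// Monte Carlo restraint satisfaction, Langevin (BAOAB) integration.
// All lengths in sigma, energies in epsilon, time in tau; bead indices
// arriving from R are 1-based and converted here.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

struct FF {
  double sigma, eps, eps_star, kappa, R0, K, r0, cutoff;
};

static FF ff_from_list(const List& p) {
  FF f;
  f.sigma    = as<double>(p["sigma"]);
  f.eps      = as<double>(p["epsilon"]);
  f.eps_star = as<double>(p["epsilon_star"]);
  f.kappa    = as<double>(p["kappa"]);
  f.R0       = as<double>(p["R0"]);
  f.K        = as<double>(p["K"]);
  f.r0       = as<double>(p["r0"]);
  f.cutoff   = as<double>(p["lj_cutoff"]);
  return f;
}

// WCA: 4 e [(s/r)^12 - (s/r)^6 + 1/4] for r <= 2^(1/6) s, else 0.
static inline double wca_energy(double r, double sigma, double eps,
                                double cutoff) {
  if (r > cutoff) return 0.0;
  double sr2 = (sigma * sigma) / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6 + 0.25);
}

// radial force F = -dU/dr (positive = repulsive)
static inline double wca_force(double r, double sigma, double eps,
                               double cutoff) {
  if (r > cutoff) return 0.0;
  double sr2 = (sigma * sigma) / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r;
}

static inline double fene_energy(double r, const FF& f) {
  double x = r / f.R0;
  if (x >= 1.0) return std::numeric_limits<double>::infinity();
  return -0.5 * f.kappa * f.R0 * f.R0 * std::log(1.0 - x * x);
}

static inline double fene_force(double r, const FF& f) {
  double x = r / f.R0;
  if (x >= 1.0) return -std::numeric_limits<double>::infinity();
  return -f.kappa * r / (1.0 - x * x);
}

static inline double bonded_energy_(double r, const FF& f) {
  return fene_energy(r, f) + wca_energy(r, f.sigma, f.eps_star, f.cutoff);
}

static inline double bonded_force_(double r, const FF& f) {
  return fene_force(r, f) + wca_force(r, f.sigma, f.eps_star, f.cutoff);
}

static inline double restraint_energy_(double r, const FF& f) {
  double d = r - f.r0;
  return f.K * d * d;
}

static inline double restraint_force_(double r, const FF& f) {
  return -2.0 * f.K * (r - f.r0);
}

// [[Rcpp::export]]
NumericVector cpp_bonded_energy(NumericVector r, List params) {
  FF f = ff_from_list(params);
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = bonded_energy_(r[i], f);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bonded_force(NumericVector r, List params) {
  FF f = ff_from_list(params);
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = bonded_force_(r[i], f);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nonbonded_energy(NumericVector r, List params) {
  FF f = ff_from_list(params);
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i)
    out[i] = wca_energy(r[i], f.sigma, f.eps, f.cutoff);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nonbonded_force(NumericVector r, List params) {
  FF f = ff_from_list(params);
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i)
    out[i] = wca_force(r[i], f.sigma, f.eps, f.cutoff);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_restraint_energy(NumericVector r, List params) {
  FF f = ff_from_list(params);
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = restraint_energy_(r[i], f);
  return out;
}

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Total energy and per-bead forces.  pos is N x 3; restr is R x 2
// (0-based, i+1 < j).  Bonded pairs are consecutive beads; nonbonded
// pairs are all |i-j| > 1 within the WCA cutoff; restrained pairs add
// the harmonic term on top of their nonbonded interaction.
static double energy_forces(const NumericMatrix& pos,
                            const IntegerMatrix& restr, const FF& f,
                            NumericMatrix& force, bool want_force,
                            int* bad_bond) {
  const int n = pos.nrow();
  double e = 0.0;
  if (want_force) std::fill(force.begin(), force.end(), 0.0);
  if (bad_bond) *bad_bond = -1;
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pos(i, 0); P[3 * i + 1] = pos(i, 1); P[3 * i + 2] = pos(i, 2);
  }
  double cut2 = f.cutoff * f.cutoff;
  // bonded
  for (int i = 0; i + 1 < n; ++i) {
    double r = dist3(&P[3 * i], &P[3 * (i + 1)]);
    if (r >= f.R0) { if (bad_bond) { *bad_bond = i; } return R_PosInf; }
    e += bonded_energy_(r, f);
    if (want_force) {
      double fr = bonded_force_(r, f) / r;
      for (int d = 0; d < 3; ++d) {
        double c = fr * (P[3 * i + d] - P[3 * (i + 1) + d]);
        force(i, d) += c; force(i + 1, d) -= c;
      }
    }
  }
  // nonbonded (all-pairs screen on squared distance)
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = P[3 * i] - P[3 * j];
      double dy = P[3 * i + 1] - P[3 * j + 1];
      double dz = P[3 * i + 2] - P[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      e += wca_energy(r, f.sigma, f.eps, f.cutoff);
      if (want_force) {
        double fr = wca_force(r, f.sigma, f.eps, f.cutoff) / r;
        force(i, 0) += fr * dx; force(j, 0) -= fr * dx;
        force(i, 1) += fr * dy; force(j, 1) -= fr * dy;
        force(i, 2) += fr * dz; force(j, 2) -= fr * dz;
      }
    }
  }
  // restraints
  for (int k = 0; k < restr.nrow(); ++k) {
    int i = restr(k, 0), j = restr(k, 1);
    double r = dist3(&P[3 * i], &P[3 * j]);
    e += restraint_energy_(r, f);
    if (want_force && r > 0) {
      double fr = restraint_force_(r, f) / r;
      for (int d = 0; d < 3; ++d) {
        double c = fr * (P[3 * i + d] - P[3 * j + d]);
        force(i, d) += c; force(j, d) -= c;
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_system_energy_forces(NumericMatrix pos, IntegerMatrix restr,
                              List params) {
  FF f = ff_from_list(params);
  NumericMatrix force(pos.nrow(), 3);
  int bad = -1;
  double e = energy_forces(pos, restr, f, force, true, &bad);
  return List::create(_["energy"] = e, _["forces"] = force,
                      _["bad_bond"] = bad + 1);
}

static inline void rand_unit(double* u) {
  double n2 = 0.0;
  do {
    n2 = 0.0;
    for (int d = 0; d < 3; ++d) { u[d] = norm_rand(); n2 += u[d] * u[d]; }
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  for (int d = 0; d < 3; ++d) u[d] *= inv;
}

// Self-avoiding random walk by incremental growth with rejection and
// bounded backtracking.  Optional spherical confinement and a set of
// fixed obstacle beads (used by the synthetic reference structures).
// Returns N x 3 matrix, or stops when the backtrack budget is spent.
// [[Rcpp::export]]
NumericMatrix cpp_sarw(int n_beads, double bond_length,
                       double excluded_radius, NumericVector start,
                       bool confined, NumericVector center, double radius,
                       NumericMatrix obstacles, int max_backtrack,
                       int tries_per_bead) {
  std::vector<double> P(3 * n_beads);
  for (int d = 0; d < 3; ++d) P[d] = start[d];
  const double ex2 = excluded_radius * excluded_radius;
  const int n_obs = obstacles.nrow();
  int k = 1, backtracks = 0;
  double u[3];
  while (k < n_beads) {
    bool placed = false;
    for (int t = 0; t < tries_per_bead; ++t) {
      rand_unit(u);
      double cand[3];
      for (int d = 0; d < 3; ++d)
        cand[d] = P[3 * (k - 1) + d] + bond_length * u[d];
      if (confined) {
        double dc2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dd = cand[d] - center[d]; dc2 += dd * dd;
        }
        if (dc2 > radius * radius) continue;
      }
      bool clash = false;
      for (int j = 0; j < k - 1 && !clash; ++j) {
        double dx = cand[0] - P[3 * j], dy = cand[1] - P[3 * j + 1],
               dz = cand[2] - P[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < ex2) clash = true;
      }
      for (int j = 0; j < n_obs && !clash; ++j) {
        double dx = cand[0] - obstacles(j, 0), dy = cand[1] - obstacles(j, 1),
               dz = cand[2] - obstacles(j, 2);
        if (dx * dx + dy * dy + dz * dz < ex2) clash = true;
      }
      if (!clash) {
        for (int d = 0; d < 3; ++d) P[3 * k + d] = cand[d];
        ++k; placed = true;
        break;
      }
    }
    if (!placed) {
      if (++backtracks > max_backtrack)
        stop("self-avoiding walk exhausted its backtrack budget (%d); "
             "increase bond_length/excluded_radius ratio or the budget",
             max_backtrack);
      if (k > 1) --k;  // retract the previous bead and regrow
    }
  }
  NumericMatrix out(n_beads, 3);
  for (int i = 0; i < n_beads; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = P[3 * i + d];
  return out;
}

// Energy of bead b against the rest of the system (bonds to b-1/b+1,
// nonbonded within cutoff, active harmonic restraints touching b).
static double local_energy(const std::vector<double>& P, int n, int b,
                           const double* pb, const FF& f,
                           const IntegerMatrix& restr,
                           const std::vector<std::vector<int> >& radj,
                           const std::vector<char>& active,
                           const std::vector<char>& satisfied,
                           double pull_stiffness, double pull_factor,
                           double wca_cap) {
  double e = 0.0;
  const double cut2 = f.cutoff * f.cutoff;
  for (int nb = b - 1; nb <= b + 1; nb += 2) {
    if (nb < 0 || nb >= n) continue;
    double dx = pb[0] - P[3 * nb], dy = pb[1] - P[3 * nb + 1],
           dz = pb[2] - P[3 * nb + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r >= f.R0) return R_PosInf;
    e += bonded_energy_(r, f);
  }
  for (int j = 0; j < n; ++j) {
    if (std::abs(j - b) <= 1) continue;
    double dx = pb[0] - P[3 * j], dy = pb[1] - P[3 * j + 1],
           dz = pb[2] - P[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < cut2)
      e += std::min(wca_energy(std::sqrt(r2), f.sigma, f.eps, f.cutoff),
                    wca_cap);
  }
  for (size_t m = 0; m < radj[b].size(); ++m) {
    int k = radj[b][m];
    if (!active[k]) continue;
    int other = (restr(k, 0) == b) ? restr(k, 1) : restr(k, 0);
    double dx = pb[0] - P[3 * other], dy = pb[1] - P[3 * other + 1],
           dz = pb[2] - P[3 * other + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (satisfied[k]) {
      e += restraint_energy_(r, f);
    } else {
      // not yet connected: temporarily stiffer, shorter spring that
      // guarantees a dip below the activation radius; reverts to the
      // standard harmonic permanently once the pair first connects
      double d = r - pull_factor * f.r0;
      e += pull_stiffness * f.K * d * d;
    }
  }
  return e;
}

// Metropolis single-bead-move Monte Carlo driving all restrained pairs
// to within `activation`.  Restraints arrive sorted by genomic
// separation; they are switched on in `n_stages` batches and a pair is
// marked satisfied (sticky) the first time it dips to <= activation.
// [[Rcpp::export]]
List cpp_mc_fold(NumericMatrix pos, IntegerMatrix restr, List params,
                 double move_sigma, double temperature, int max_sweeps,
                 double activation, int n_stages, double pull_stiffness,
                 double pull_factor, double wca_cap) {
  FF f = ff_from_list(params);
  const int n = pos.nrow(), nr = restr.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) P[3 * i + d] = pos(i, d);
  std::vector<std::vector<int> > radj(n);
  for (int k = 0; k < nr; ++k) {
    radj[restr(k, 0)].push_back(k);
    radj[restr(k, 1)].push_back(k);
  }
  std::vector<char> active(nr, 0), satisfied(nr, 0);
  if (n_stages < 1) n_stages = 1;
  if (n_stages > nr && nr > 0) n_stages = nr;
  int stage = 0;
  int n_active = 0;
  double max_bond_seen = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double r = dist3(&P[3 * i], &P[3 * (i + 1)]);
    if (r > max_bond_seen) max_bond_seen = r;
  }
  long accepted = 0, attempted = 0;
  int sweeps_used = 0;

  // activate batch `stage` (restraints are pre-sorted by |i-j|)
  // stage s covers indices [0, ceil((s+1)/n_stages * nr))
  #define ACTIVATE_STAGE(s) do { \
    int upto = (int)std::ceil((double)((s) + 1) / n_stages * nr); \
    for (int k = 0; k < upto; ++k) active[k] = 1; \
    n_active = upto; } while (0)

  if (nr > 0) ACTIVATE_STAGE(0);

  // sticky satisfaction check over active restraints
  auto check_satisfied = [&](void) -> bool {
    bool all = true;
    for (int k = 0; k < n_active; ++k) {
      if (satisfied[k]) continue;
      double r = dist3(&P[3 * restr(k, 0)], &P[3 * restr(k, 1)]);
      if (r <= activation) satisfied[k] = 1; else all = false;
    }
    return all;
  };

  bool done = (nr == 0);
  // sweep-0 check: pairs already within activation count as satisfied;
  // advance through stages only while each new batch is satisfied too
  while (!done && check_satisfied()) {
    if (stage + 1 < n_stages) { ++stage; ACTIVATE_STAGE(stage); }
    else done = true;
  }
  for (int sweep = 0; sweep < max_sweeps && !done; ++sweep) {
    sweeps_used = sweep + 1;
    for (int b = 0; b < n; ++b) {
      double old[3] = {P[3 * b], P[3 * b + 1], P[3 * b + 2]};
      double cand[3];
      for (int d = 0; d < 3; ++d)
        cand[d] = old[d] + move_sigma * norm_rand();
      double e_old = local_energy(P, n, b, old, f, restr, radj, active,
                                  satisfied, pull_stiffness, pull_factor,
                                  wca_cap);
      double e_new = local_energy(P, n, b, cand, f, restr, radj, active,
                                  satisfied, pull_stiffness, pull_factor,
                                  wca_cap);
      ++attempted;
      if (!std::isfinite(e_new)) continue;  // would break a bond
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / temperature)) {
        for (int d = 0; d < 3; ++d) P[3 * b + d] = cand[d];
        ++accepted;
        for (int nb = b - 1; nb <= b; ++nb) {
          if (nb < 0 || nb + 1 >= n) continue;
          double r = dist3(&P[3 * nb], &P[3 * (nb + 1)]);
          if (r > max_bond_seen) max_bond_seen = r;
        }
      }
    }
    while (!done && check_satisfied()) {
      if (stage + 1 < n_stages) { ++stage; ACTIVATE_STAGE(stage); }
      else done = true;
    }
    if ((sweep & 63) == 0) Rcpp::checkUserInterrupt();
  }
  #undef ACTIVATE_STAGE

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = P[3 * i + d];
  NumericVector final_dist(nr);
  LogicalVector sat(nr);
  int n_unsat = 0;
  double worst = 0.0;
  for (int k = 0; k < nr; ++k) {
    final_dist[k] = dist3(&P[3 * restr(k, 0)], &P[3 * restr(k, 1)]);
    sat[k] = satisfied[k] != 0;
    if (!satisfied[k]) {
      ++n_unsat;
      if (final_dist[k] > worst) worst = final_dist[k];
    }
  }
  return List::create(
      _["positions"] = out, _["satisfied"] = sat,
      _["final_distances"] = final_dist, _["sweeps"] = sweeps_used,
      _["converged"] = done, _["n_unsatisfied"] = n_unsat,
      _["worst_distance"] = worst,
      _["acceptance_rate"] = attempted ? (double)accepted / attempted : NA_REAL,
      _["max_bond_seen"] = max_bond_seen);
}

// Langevin dynamics by the BAOAB splitting (exact Ornstein-Uhlenbeck
// velocity update); reduces to velocity Verlet when gamma = 0.
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix pos, NumericMatrix vel0,
                  IntegerMatrix restr, List params, int n_steps,
                  double dt, double gamma, double temperature, double mass,
                  int stride) {
  FF f = ff_from_list(params);
  const int n = pos.nrow();
  NumericMatrix x(clone(pos)), v(clone(vel0)), force(n, 3);
  int bad = -1;
  double e = energy_forces(x, restr, f, force, true, &bad);
  if (!std::isfinite(e))
    stop("non-finite energy in the initial configuration (bond %d)", bad + 1);
  const double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 =
      (gamma > 0.0) ? std::sqrt(temperature / mass * (1.0 - c1 * c1)) : 0.0;
  const int n_snap = (stride > 0) ? n_steps / stride : 0;
  List snapshots(n_snap);
  NumericVector temps(n_snap);
  int isnap = 0;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i, d) += 0.5 * dt * force(i, d) / mass;       // B
        x(i, d) += 0.5 * dt * v(i, d);                  // A
      }
    if (c2 > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          v(i, d) = c1 * v(i, d) + c2 * norm_rand();    // O
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);  // A
    e = energy_forces(x, restr, f, force, true, &bad);
    if (!std::isfinite(e))
      stop("energy diverged at step %d (bond %d beyond maximum extension)",
           step + 1, bad + 1);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) += 0.5 * dt * force(i, d) / mass;       // B
    if (stride > 0 && ((step + 1) % stride == 0) && isnap < n_snap) {
      double ke = 0.0;
      bool blown = false;
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          snap(i, d) = x(i, d);
          if (std::abs(x(i, d)) > 1e6) blown = true;
          ke += v(i, d) * v(i, d);
        }
      if (blown)
        stop("coordinate exceeded 1e6 sigma at step %d", step + 1);
      temps[isnap] = mass * ke / (3.0 * n);
      snapshots[isnap] = snap;
      ++isnap;
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  double ke = 0.0;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) ke += v(i, d) * v(i, d);
  return List::create(_["positions"] = x, _["velocities"] = v,
                      _["snapshots"] = snapshots, _["temps"] = temps,
                      _["final_energy"] = e,
                      _["final_kinetic"] = 0.5 * mass * ke);
}

// Steepest-descent energy minimization with a per-step displacement
// cap; used between the MC stage (which may leave soft overlaps when
// run with a capped repulsion) and the dynamics.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, IntegerMatrix restr, List params,
                  int max_steps, double max_disp, double force_tol) {
  FF f = ff_from_list(params);
  const int n = pos.nrow();
  NumericMatrix x(clone(pos)), force(n, 3), trial(n, 3);
  int bad = -1;
  double e = energy_forces(x, restr, f, force, true, &bad);
  double h = 1e-3;
  int step = 0;
  for (; step < max_steps; ++step) {
    double fmax = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        fmax = std::max(fmax, std::abs(force(i, d)));
    if (fmax < force_tol) break;
    double scale = h;
    if (scale * fmax > max_disp) scale = max_disp / fmax;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        trial(i, d) = x(i, d) + scale * force(i, d);
    NumericMatrix tforce(n, 3);
    double et = energy_forces(trial, restr, f, tforce, true, &bad);
    if (std::isfinite(et) && et <= e) {
      x = clone(trial);
      force = clone(tforce);
      e = et;
      h *= 1.2;
    } else {
      h *= 0.5;
      if (h < 1e-12) break;
    }
    if ((step & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["positions"] = x, _["energy"] = e,
                      _["steps"] = step);
}
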