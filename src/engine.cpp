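// Desk-scale Langevin dynamics core.
//
// Units: Angstrom, fs, amu, kcal/mol, elementary charges, Kelvin
// (the LAMMPS "real" convention). Forces are analytic derivatives of the
// Wang-Frenkel / repulsive-variant / Yukawa pair terms plus harmonic
// bonds; the integrator is BAOAB Langevin splitting, which reduces to
// velocity Verlet when the friction is zero.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0019872041;           // kcal/(mol K)
static const double MVV2E = 48.88821291 * 48.88821291;
static const double FTM2V = 1.0 / MVV2E;         // (amu A/fs^2) per kcal/mol/A

struct PairTables {
  int ntypes;
  // ntypes x ntypes, row-major, symmetric
  std::vector<double> eps, sigma, mu2, nu2, rcut, alpha, rstar, qq;
  double kappa, ycut, max_cut;
  bool yshift;
};

static inline int idx2(int i, int j, int n) { return i * n + j; }

// Wang-Frenkel value and d/dr for the unclipped form (any sign of eps).
static inline void wf_raw(double r, double eps, double sig, double m2,
                          double n2, double R, double alpha, double &u,
                          double &du) {
  double f = std::pow(sig / r, m2) - 1.0;
  double g = std::pow(R / r, m2) - 1.0;
  double gn = std::pow(g, n2);
  u = eps * alpha * f * gn;
  double fp = -m2 * std::pow(sig, m2) * std::pow(r, -m2 - 1.0);
  double gp = -m2 * std::pow(R, m2) * std::pow(r, -m2 - 1.0);
  du = eps * alpha * (fp * gn + n2 * f * std::pow(g, n2 - 1.0) * gp);
}

// Accumulate energy and force magnitude (as -dU/dr) for one pair at
// separation r given flattened type-pair tables.
static inline void pair_eval(double r, int ti, int tj, const PairTables &pt,
                             double &u, double &fmag) {
  u = 0.0; fmag = 0.0;
  int k = idx2(ti, tj, pt.ntypes);
  double eps = pt.eps[k];
  if (eps != 0.0) {
    if (eps > 0.0) {
      if (r < pt.rcut[k]) {
        double uu, du;
        wf_raw(r, eps, pt.sigma[k], pt.mu2[k], pt.nu2[k], pt.rcut[k],
               pt.alpha[k], uu, du);
        u += uu; fmag += -du;
      }
    } else {
      if (r < pt.rstar[k]) {
        double uu, du;
        wf_raw(r, eps, pt.sigma[k], pt.mu2[k], pt.nu2[k], pt.rcut[k],
               pt.alpha[k], uu, du);
        u += -uu - eps;          // WCA-style shift: zero at r*
        fmag += du;              // -d/dr(-phi) = +dphi/dr
      }
    }
  }
  double qq = pt.qq[k];
  if (qq != 0.0 && r < pt.ycut) {
    double ex = std::exp(-pt.kappa * r);
    double uy = qq * ex / r;
    if (pt.yshift) uy -= qq * std::exp(-pt.kappa * pt.ycut) / pt.ycut;
    u += uy;
    fmag += qq * ex * (pt.kappa * r + 1.0) / (r * r);
  }
}

static PairTables unpack_tables(const List &tables) {
  PairTables pt;
  pt.ntypes = as<int>(tables["ntypes"]);
  pt.eps = as<std::vector<double>>(tables["eps"]);
  pt.sigma = as<std::vector<double>>(tables["sigma"]);
  pt.mu2 = as<std::vector<double>>(tables["mu2"]);
  pt.nu2 = as<std::vector<double>>(tables["nu2"]);
  pt.rcut = as<std::vector<double>>(tables["rcut"]);
  pt.alpha = as<std::vector<double>>(tables["alpha"]);
  pt.rstar = as<std::vector<double>>(tables["rstar"]);
  pt.qq = as<std::vector<double>>(tables["qq"]);
  pt.kappa = as<double>(tables["kappa"]);
  pt.ycut = as<double>(tables["ycut"]);
  pt.yshift = as<bool>(tables["yshift"]);
  pt.max_cut = as<double>(tables["max_cut"]);
  return pt;
}

struct System {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, mass;
  std::vector<int> type;        // 0-based
  double box[3];
  // bonds
  std::vector<int> b1, b2;      // 0-based
  double bond_r0, bond_k;
  // bonded-neighbour exclusion sets (small)
  std::vector<std::vector<int>> excl;
};

static System unpack_system(const NumericMatrix &pos,
                            const NumericMatrix &vel,
                            const NumericVector &mass,
                            const IntegerVector &type,
                            const NumericVector &box,
                            const IntegerMatrix &bonds, double bond_r0,
                            double bond_k) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.vx.resize(s.n); s.vy.resize(s.n); s.vz.resize(s.n);
  s.mass.resize(s.n); s.type.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    s.mass[i] = mass[i]; s.type[i] = type[i] - 1;
  }
  for (int d = 0; d < 3; ++d) s.box[d] = box[d];
  s.bond_r0 = bond_r0; s.bond_k = bond_k;
  s.excl.resize(s.n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    s.b1.push_back(i); s.b2.push_back(j);
    s.excl[i].push_back(j); s.excl[j].push_back(i);
  }
  return s;
}

static inline bool excluded(const System &s, int i, int j) {
  for (int k : s.excl[i]) if (k == j) return true;
  return false;
}

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// All-pairs force/energy evaluation.
static double forces_allpairs(const System &s, const PairTables &pt,
                              std::vector<double> &fx,
                              std::vector<double> &fy,
                              std::vector<double> &fz) {
  double etot = 0.0;
  for (int i = 0; i < s.n; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      if (excluded(s, i, j)) continue;
      double dx = min_image(s.x[i] - s.x[j], s.box[0]);
      double dy = min_image(s.y[i] - s.y[j], s.box[1]);
      double dz = min_image(s.z[i] - s.z[j], s.box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pt.max_cut * pt.max_cut) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) stop("overlapping beads (r ~ 0)");
      double u, fm;
      pair_eval(r, s.type[i], s.type[j], pt, u, fm);
      etot += u;
      double fr = fm / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }
  return etot;
}

// Cell-list evaluation; requires >= 3 cells per dimension, else the caller
// must fall back to all-pairs.
static double forces_celllist(const System &s, const PairTables &pt,
                              std::vector<double> &fx,
                              std::vector<double> &fy,
                              std::vector<double> &fz) {
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)std::floor(s.box[d] / pt.max_cut);
    if (nc[d] < 3) stop("cell list requires >= 3 cells per dimension");
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), next(s.n, -1);
  std::vector<int> cix(s.n), ciy(s.n), ciz(s.n);
  for (int i = 0; i < s.n; ++i) {
    double wx = s.x[i] - std::floor(s.x[i] / s.box[0]) * s.box[0];
    double wy = s.y[i] - std::floor(s.y[i] / s.box[1]) * s.box[1];
    double wz = s.z[i] - std::floor(s.z[i] / s.box[2]) * s.box[2];
    int ix = std::min((int)(wx / s.box[0] * nc[0]), nc[0] - 1);
    int iy = std::min((int)(wy / s.box[1] * nc[1]), nc[1] - 1);
    int iz = std::min((int)(wz / s.box[2] * nc[2]), nc[2] - 1);
    cix[i] = ix; ciy[i] = iy; ciz[i] = iz;
    int c = (ix * nc[1] + iy) * nc[2] + iz;
    next[i] = head[c]; head[c] = i;
  }
  double etot = 0.0;
  for (int i = 0; i < s.n; ++i) {
    for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy)
      for (int oz = -1; oz <= 1; ++oz) {
        int jx = (cix[i] + ox + nc[0]) % nc[0];
        int jy = (ciy[i] + oy + nc[1]) % nc[1];
        int jz = (ciz[i] + oz + nc[2]) % nc[2];
        int c = (jx * nc[1] + jy) * nc[2] + jz;
        for (int j = head[c]; j != -1; j = next[j]) {
          if (j <= i) continue;
          if (excluded(s, i, j)) continue;
          double dx = min_image(s.x[i] - s.x[j], s.box[0]);
          double dy = min_image(s.y[i] - s.y[j], s.box[1]);
          double dz = min_image(s.z[i] - s.z[j], s.box[2]);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= pt.max_cut * pt.max_cut) continue;
          double r = std::sqrt(r2);
          if (r < 1e-12) stop("overlapping beads (r ~ 0)");
          double u, fm;
          pair_eval(r, s.type[i], s.type[j], pt, u, fm);
          etot += u;
          double fr = fm / r;
          fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
          fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        }
      }
  }
  return etot;
}

// Bond terms: U = k (r - r0)^2.
static double forces_bonds(const System &s, std::vector<double> &fx,
                           std::vector<double> &fy, std::vector<double> &fz) {
  double etot = 0.0;
  for (size_t b = 0; b < s.b1.size(); ++b) {
    int i = s.b1[b], j = s.b2[b];
    double dx = min_image(s.x[i] - s.x[j], s.box[0]);
    double dy = min_image(s.y[i] - s.y[j], s.box[1]);
    double dz = min_image(s.z[i] - s.z[j], s.box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - s.bond_r0;
    etot += s.bond_k * dr * dr;
    double fm = -2.0 * s.bond_k * dr;      // -dU/dr
    double fr = (r > 1e-12) ? fm / r : 0.0;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  return etot;
}

static double compute_all(const System &s, const PairTables &pt,
                          bool use_cell, std::vector<double> &fx,
                          std::vector<double> &fy, std::vector<double> &fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  bool cell_ok = use_cell;
  if (use_cell) {
    for (int d = 0; d < 3; ++d) {
      if (std::floor(s.box[d] / pt.max_cut) < 3) cell_ok = false;
    }
  }
  double e = cell_ok ? forces_celllist(s, pt, fx, fy, fz)
                     : forces_allpairs(s, pt, fx, fy, fz);
  e += forces_bonds(s, fx, fy, fz);
  return e;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericMatrix vel,
                       NumericVector mass, IntegerVector type,
                       NumericVector box, IntegerMatrix bonds,
                       double bond_r0, double bond_k, List tables,
                       bool use_cell) {
  System s = unpack_system(pos, vel, mass, type, box, bonds, bond_r0, bond_k);
  PairTables pt = unpack_tables(tables);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  double e = compute_all(s, pt, use_cell, fx, fy, fz);
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i];
  }
  return List::create(_["energy"] = e, _["forces"] = f);
}

// BAOAB Langevin integrator. friction in 1/fs (0 = NVE velocity Verlet).
// Positions evolve unwrapped; minimum-image convention handles periodicity.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                IntegerVector type, NumericVector box, IntegerMatrix bonds,
                double bond_r0, double bond_k, List tables, double dt,
                double friction, double temperature, int n_steps,
                int seed, bool use_cell, int sample_every) {
  System s = unpack_system(pos, vel, mass, type, box, bonds, bond_r0, bond_k);
  PairTables pt = unpack_tables(tables);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  double pe = compute_all(s, pt, use_cell, fx, fy, fz);
  std::vector<double> samp_pe, samp_ke;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  double c2 = (friction > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  double half_min_box =
      0.5 * std::min(s.box[0], std::min(s.box[1], s.box[2]));

  for (int step = 0; step < n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < s.n; ++i) {
      double a = 0.5 * dt * FTM2V / s.mass[i];
      s.vx[i] += a * fx[i]; s.vy[i] += a * fy[i]; s.vz[i] += a * fz[i];
    }
    // A: half drift (with instability guard)
    for (int i = 0; i < s.n; ++i) {
      double ddx = 0.5 * dt * s.vx[i];
      double ddy = 0.5 * dt * s.vy[i];
      double ddz = 0.5 * dt * s.vz[i];
      if (std::fabs(ddx) > half_min_box || std::fabs(ddy) > half_min_box ||
          std::fabs(ddz) > half_min_box)
        stop("integration unstable: displacement exceeds half the box");
      s.x[i] += ddx; s.y[i] += ddy; s.z[i] += ddz;
    }
    // O: Ornstein-Uhlenbeck velocity update
    if (friction > 0.0) {
      for (int i = 0; i < s.n; ++i) {
        double sv = std::sqrt(KB * temperature * FTM2V / s.mass[i]);
        s.vx[i] = c1 * s.vx[i] + c2 * sv * gauss(rng);
        s.vy[i] = c1 * s.vy[i] + c2 * sv * gauss(rng);
        s.vz[i] = c1 * s.vz[i] + c2 * sv * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < s.n; ++i) {
      s.x[i] += 0.5 * dt * s.vx[i];
      s.y[i] += 0.5 * dt * s.vy[i];
      s.z[i] += 0.5 * dt * s.vz[i];
    }
    // recompute forces, B: half kick
    pe = compute_all(s, pt, use_cell, fx, fy, fz);
    for (int i = 0; i < s.n; ++i) {
      double a = 0.5 * dt * FTM2V / s.mass[i];
      s.vx[i] += a * fx[i]; s.vy[i] += a * fy[i]; s.vz[i] += a * fz[i];
    }
    if (sample_every > 0 && (step + 1) % sample_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < s.n; ++i) {
        ke += 0.5 * s.mass[i] *
              (s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i]);
      }
      samp_pe.push_back(pe);
      samp_ke.push_back(ke * MVV2E);
    }
  }

  NumericMatrix posout(s.n, 3), velout(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    posout(i, 0) = s.x[i]; posout(i, 1) = s.y[i]; posout(i, 2) = s.z[i];
    velout(i, 0) = s.vx[i]; velout(i, 1) = s.vy[i]; velout(i, 2) = s.vz[i];
  }
  return List::create(_["positions"] = posout, _["velocities"] = velout,
                      _["sample_pe"] = wrap(samp_pe),
                      _["sample_ke"] = wrap(samp_ke));
}
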