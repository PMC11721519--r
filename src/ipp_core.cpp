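// Core numerics for the IPP model: closed-form lens volumes, the
// anisotropic pair energy, cell-list energies, the grand-canonical
// Metropolis engine and the bonding-volume Monte Carlo integrator.
// All randomness is drawn from R's RNG (unif_rand) so a set.seed() on the
// R side makes every run bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double INF_E = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- geometry

struct Geom {
  double sigma_c, delta, a, sigma_p, Rc, r_core, r_cut;
};

static Geom as_geom(const List &g) {
  Geom G;
  G.sigma_c = as<double>(g["sigma_c"]);
  G.delta   = as<double>(g["delta"]);
  G.a       = as<double>(g["a"]);
  G.sigma_p = as<double>(g["sigma_p"]);
  G.Rc      = as<double>(g["R_c"]);
  G.r_core  = as<double>(g["r_core"]);
  G.r_cut   = as<double>(g["r_cut"]);
  return G;
}

// lens volume of spheres (R1, R2) at centre distance d
static inline double lens(double R1, double R2, double d) {
  double s = R1 + R2;
  if (d >= s) return 0.0;
  double ad = std::fabs(R1 - R2);
  if (d <= ad) {
    double rm = (R1 < R2) ? R1 : R2;
    return (4.0 / 3.0) * M_PI * rm * rm * rm;
  }
  double h = s - d;
  return M_PI * h * h * (d * d + 2.0 * d * s - 3.0 * (R1 - R2) * (R1 - R2)) / (12.0 * d);
}

// pair energy given displacement (dx,dy,dz) = r2 - r1 (minimum image
// already applied), unit axes n1, n2. Returns +Inf on hard-core overlap.
static double pair_u(double dx, double dy, double dz,
                     const double *n1, const double *n2,
                     const Geom &G, const double *eps) {
  double r2 = dx * dx + dy * dy + dz * dz;
  double rc2 = G.r_cut * G.r_cut;
  if (r2 > rc2) return 0.0;
  double r = std::sqrt(r2);
  if (r < G.r_core - 1e-12) return INF_E;
  double a = G.a;
  double w_cc = lens(G.Rc, G.Rc, r);
  double w_cp = 0.0, w_pp = 0.0;
  double scp = G.Rc + G.sigma_p, spp = 2.0 * G.sigma_p;
  for (int s = -1; s <= 1; s += 2) {
    // centre 1 - patch of 2 at r_vec + s*a*n2
    double ux = dx + s * a * n2[0], uy = dy + s * a * n2[1], uz = dz + s * a * n2[2];
    double d2 = ux * ux + uy * uy + uz * uz;
    if (d2 < scp * scp) w_cp += lens(G.Rc, G.sigma_p, std::sqrt(d2));
    // centre 2 - patch of 1 at s*a*n1 (distance to r_vec)
    double vx = dx - s * a * n1[0], vy = dy - s * a * n1[1], vz = dz - s * a * n1[2];
    double e2 = vx * vx + vy * vy + vz * vz;
    if (e2 < scp * scp) w_cp += lens(G.Rc, G.sigma_p, std::sqrt(e2));
  }
  for (int s1 = -1; s1 <= 1; s1 += 2) {
    for (int s2 = -1; s2 <= 1; s2 += 2) {
      double px = dx + a * (s2 * n2[0] - s1 * n1[0]);
      double py = dy + a * (s2 * n2[1] - s1 * n1[1]);
      double pz = dz + a * (s2 * n2[2] - s1 * n1[2]);
      double d2 = px * px + py * py + pz * pz;
      if (d2 < spp * spp) w_pp += lens(G.sigma_p, G.sigma_p, std::sqrt(d2));
    }
  }
  return eps[0] * w_cc + eps[1] * w_cp + eps[2] * w_pp;
}

// [[Rcpp::export(name = ".pair_energy_cpp")]]
double pair_energy_cpp(NumericVector r_vec, NumericVector n1, NumericVector n2,
                       List geom, NumericVector eps) {
  Geom G = as_geom(geom);
  return pair_u(r_vec[0], r_vec[1], r_vec[2], &n1[0], &n2[0], G, &eps[0]);
}

// ------------------------------------------------------------- cell system

struct Box {
  double L;
  int M;          // cells per dimension (1 => no cell list, all pairs)
  double cellw;
  std::vector<int> head;           // M^3
  std::vector<int> nxt;            // per particle
  std::vector<double> x, y, z, ax, ay, az;
  int N;

  void init(double L_, double range, int cap) {
    L = L_;
    M = (int)std::floor(L / range);
    if (M < 3) M = 1;
    cellw = L / M;
    head.assign(M * M * M, -1);
    nxt.assign(cap, -1);
    x.assign(cap, 0.0); y.assign(cap, 0.0); z.assign(cap, 0.0);
    ax.assign(cap, 0.0); ay.assign(cap, 0.0); az.assign(cap, 0.0);
    N = 0;
  }
  inline int cell_of(double px, double py, double pz) const {
    if (M == 1) return 0;
    int cx = (int)(px / cellw), cy = (int)(py / cellw), cz = (int)(pz / cellw);
    if (cx >= M) cx = M - 1; if (cy >= M) cy = M - 1; if (cz >= M) cz = M - 1;
    return (cx * M + cy) * M + cz;
  }
  inline void mi(double &dx, double &dy, double &dz) const {
    dx -= L * std::round(dx / L);
    dy -= L * std::round(dy / L);
    dz -= L * std::round(dz / L);
  }
  void insert_cell(int i) {
    int c = cell_of(x[i], y[i], z[i]);
    nxt[i] = head[c]; head[c] = i;
  }
  void remove_cell(int i) {
    int c = cell_of(x[i], y[i], z[i]);
    int j = head[c];
    if (j == i) { head[c] = nxt[i]; return; }
    while (nxt[j] != i) j = nxt[j];
    nxt[j] = nxt[i];
  }
  // energy of a trial particle at (px,py,pz) with axis n, excluding index
  // `excl` (-1 for none). Returns +Inf on hard-core overlap.
  double one_energy(double px, double py, double pz, const double *n,
                    const Geom &G, const double *eps, int excl) const {
    double e = 0.0;
    if (M == 1) {
      for (int j = 0; j < N; ++j) {
        if (j == excl) continue;
        double dx = x[j] - px, dy = y[j] - py, dz = z[j] - pz;
        mi(dx, dy, dz);
        double nj[3] = {ax[j], ay[j], az[j]};
        double u = pair_u(dx, dy, dz, n, nj, G, eps);
        if (u == INF_E) return INF_E;
        e += u;
      }
      return e;
    }
    int cx = (int)(px / cellw), cy = (int)(py / cellw), cz = (int)(pz / cellw);
    if (cx >= M) cx = M - 1; if (cy >= M) cy = M - 1; if (cz >= M) cz = M - 1;
    for (int ix = -1; ix <= 1; ++ix) {
      int wx = (cx + ix + M) % M;
      for (int iy = -1; iy <= 1; ++iy) {
        int wy = (cy + iy + M) % M;
        for (int iz = -1; iz <= 1; ++iz) {
          int wz = (cz + iz + M) % M;
          for (int j = head[(wx * M + wy) * M + wz]; j != -1; j = nxt[j]) {
            if (j == excl) continue;
            double dx = x[j] - px, dy = y[j] - py, dz = z[j] - pz;
            mi(dx, dy, dz);
            double nj[3] = {ax[j], ay[j], az[j]};
            double u = pair_u(dx, dy, dz, n, nj, G, eps);
            if (u == INF_E) return INF_E;
            e += u;
          }
        }
      }
    }
    return e;
  }
  double total_energy(const Geom &G, const double *eps, bool &overlap) const {
    double e = 0.0;
    overlap = false;
    for (int i = 0; i < N; ++i) {
      double n[3] = {ax[i], ay[i], az[i]};
      // count each pair once: one_energy counts all neighbours, halve later
      double u = one_energy(x[i], y[i], z[i], n, G, eps, i);
      if (u == INF_E) { overlap = true; return INF_E; }
      e += u;
    }
    return 0.5 * e;
  }
};

// full-recompute total energy of a configuration
// [[Rcpp::export(name = ".total_energy_cpp")]]
List total_energy_cpp(NumericMatrix pos, NumericMatrix axes, double L,
                      List geom, NumericVector eps, bool hard_core = true) {
  Geom G = as_geom(geom);
  int n = pos.nrow();
  Box B;
  B.init(L, G.r_cut, n > 0 ? n : 1);
  for (int i = 0; i < n; ++i) {
    B.x[i] = pos(i, 0); B.y[i] = pos(i, 1); B.z[i] = pos(i, 2);
    B.ax[i] = axes(i, 0); B.ay[i] = axes(i, 1); B.az[i] = axes(i, 2);
    B.N++;
    B.insert_cell(i);
  }
  if (!hard_core) G.r_core = 0.0;
  bool overlap = false;
  double e = B.total_energy(G, &eps[0], overlap);
  return List::create(_["energy"] = e, _["overlap"] = overlap);
}

// uniform unit vector (Marsaglia 1972), consuming R RNG draws
static inline void rand_axis(double *n) {
  double v1, v2, s;
  do {
    v1 = 2.0 * unif_rand() - 1.0;
    v2 = 2.0 * unif_rand() - 1.0;
    s = v1 * v1 + v2 * v2;
  } while (s >= 1.0);
  double q = std::sqrt(1.0 - s);
  n[0] = 2.0 * v1 * q;
  n[1] = 2.0 * v2 * q;
  n[2] = 1.0 - 2.0 * s;
}

// rotate unit vector n by angle phi about unit axis k (Rodrigues), renormalise
static inline void rotate_about(double *n, const double *k, double phi) {
  double c = std::cos(phi), s = std::sin(phi);
  double kx = k[0], ky = k[1], kz = k[2];
  double dot = kx * n[0] + ky * n[1] + kz * n[2];
  double cx = ky * n[2] - kz * n[1];
  double cy = kz * n[0] - kx * n[2];
  double cz = kx * n[1] - ky * n[0];
  double rx = n[0] * c + cx * s + kx * dot * (1.0 - c);
  double ry = n[1] * c + cy * s + ky * dot * (1.0 - c);
  double rz = n[2] * c + cz * s + kz * dot * (1.0 - c);
  double nn = std::sqrt(rx * rx + ry * ry + rz * rz);
  n[0] = rx / nn; n[1] = ry / nn; n[2] = rz / nn;
}

// --------------------------------------------------------------- GC engine

// [[Rcpp::export(name = ".run_gcmc_cpp")]]
List run_gcmc_cpp(double L, double T, double mu,
                  int N_max, int N0,
                  double total_steps, double equil_steps,
                  double sample_every, double config_every,
                  List geom, NumericVector eps,
                  double p_exchange = 0.01,
                  double max_disp = 0.05, double max_rot = 0.1,
                  bool hard_core = true,
                  double drift_check_every = 0.0) {
  Geom G = as_geom(geom);
  if (!hard_core) G.r_core = 0.0;
  const double *ev = &eps[0];
  double beta = 1.0 / T;
  double V = L * L * L;
  double z = std::exp(mu / T); // activity, Lambda = 1 convention

  Box B;
  B.init(L, G.r_cut, N_max);

  RNGScope scope;

  // initial placement: N0 random non-overlapping particles
  if (N0 > N_max) stop("N0 exceeds N_max");
  for (int i = 0; i < N0; ++i) {
    bool placed = false;
    for (int attempt = 0; attempt < 100000; ++attempt) {
      double px = unif_rand() * L, py = unif_rand() * L, pz = unif_rand() * L;
      double n[3];
      rand_axis(n);
      // hard-core test only (orientation-independent): use one_energy with
      // zero eps would still compute weights; cheaper to test via pair_u's
      // overlap flag by calling one_energy and checking for Inf.
      double u = B.one_energy(px, py, pz, n, G, ev, -1);
      if (hard_core && u == INF_E) continue;
      int i2 = B.N;
      B.x[i2] = px; B.y[i2] = py; B.z[i2] = pz;
      B.ax[i2] = n[0]; B.ay[i2] = n[1]; B.az[i2] = n[2];
      B.N++;
      B.insert_cell(i2);
      placed = true;
      break;
    }
    if (!placed) stop("failed to place %d non-overlapping particles in box L = %g", N0, L);
  }

  bool ov0 = false;
  double E = B.total_energy(G, ev, ov0);
  if (ov0) stop("initial configuration contains hard-core overlap");

  long long n_rec = (long long)((total_steps - equil_steps) / sample_every);
  long long n_cfg = (long long)((total_steps - equil_steps) / config_every);
  NumericMatrix records(n_rec > 0 ? n_rec : 0, 3);
  List configs(n_cfg > 0 ? (R_xlen_t)n_cfg : 0);
  long long i_rec = 0, i_cfg = 0;

  // move counters: attempted / accepted for RT, insert, delete
  double att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};
  double max_drift = 0.0;

  long long tot = (long long)total_steps, eq = (long long)equil_steps;
  long long se = (long long)sample_every, ce = (long long)config_every;
  long long dce = (long long)drift_check_every;

  for (long long step = 1; step <= tot; ++step) {
    for (int mv = 0; mv < N_max; ++mv) {
      double u0 = unif_rand();
      if (u0 < p_exchange) {
        if (unif_rand() < 0.5) {
          // insertion
          att[1] += 1;
          if (B.N >= N_max) continue;
          double px = unif_rand() * L, py = unif_rand() * L, pz = unif_rand() * L;
          double n[3];
          rand_axis(n);
          double dU = B.one_energy(px, py, pz, n, G, ev, -1);
          if (dU == INF_E) continue;
          double arg = std::log(z * V / (B.N + 1)) - beta * dU;
          if (arg >= 0.0 || unif_rand() < std::exp(arg)) {
            int i2 = B.N;
            B.x[i2] = px; B.y[i2] = py; B.z[i2] = pz;
            B.ax[i2] = n[0]; B.ay[i2] = n[1]; B.az[i2] = n[2];
            B.N++;
            B.insert_cell(i2);
            E += dU;
            acc[1] += 1;
          }
        } else {
          // deletion
          att[2] += 1;
          if (B.N == 0) continue;
          int i = (int)(unif_rand() * B.N);
          if (i == B.N) i = B.N - 1;
          double n[3] = {B.ax[i], B.ay[i], B.az[i]};
          double Ui = B.one_energy(B.x[i], B.y[i], B.z[i], n, G, ev, i);
          double arg = std::log((double)B.N / (z * V)) + beta * Ui;
          if (arg >= 0.0 || unif_rand() < std::exp(arg)) {
            B.remove_cell(i);
            int last = B.N - 1;
            if (i != last) {
              B.remove_cell(last);
              B.x[i] = B.x[last]; B.y[i] = B.y[last]; B.z[i] = B.z[last];
              B.ax[i] = B.ax[last]; B.ay[i] = B.ay[last]; B.az[i] = B.az[last];
              B.insert_cell(i);
            }
            B.N--;
            E -= Ui;
            acc[2] += 1;
          }
        }
      } else {
        // rototranslation
        att[0] += 1;
        if (B.N == 0) continue;
        int i = (int)(unif_rand() * B.N);
        if (i == B.N) i = B.N - 1;
        double n_old[3] = {B.ax[i], B.ay[i], B.az[i]};
        double U_old = B.one_energy(B.x[i], B.y[i], B.z[i], n_old, G, ev, i);
        double px = B.x[i] + (2.0 * unif_rand() - 1.0) * max_disp;
        double py = B.y[i] + (2.0 * unif_rand() - 1.0) * max_disp;
        double pz = B.z[i] + (2.0 * unif_rand() - 1.0) * max_disp;
        px -= L * std::floor(px / L);
        py -= L * std::floor(py / L);
        pz -= L * std::floor(pz / L);
        double n_new[3] = {n_old[0], n_old[1], n_old[2]};
        double k[3];
        rand_axis(k);
        rotate_about(n_new, k, max_rot * unif_rand());
        double U_new = B.one_energy(px, py, pz, n_new, G, ev, i);
        if (U_new == INF_E) continue;
        double dU = U_new - U_old;
        if (dU <= 0.0 || unif_rand() < std::exp(-beta * dU)) {
          B.remove_cell(i);
          B.x[i] = px; B.y[i] = py; B.z[i] = pz;
          B.ax[i] = n_new[0]; B.ay[i] = n_new[1]; B.az[i] = n_new[2];
          B.insert_cell(i);
          E += dU;
          acc[0] += 1;
        }
      }
    }
    if (step > eq) {
      long long k = step - eq;
      if (se > 0 && k % se == 0 && i_rec < n_rec) {
        records(i_rec, 0) = (double)step;
        records(i_rec, 1) = (double)B.N;
        records(i_rec, 2) = E;
        ++i_rec;
      }
      if (ce > 0 && k % ce == 0 && i_cfg < n_cfg) {
        NumericMatrix P(B.N, 3), A(B.N, 3);
        for (int i = 0; i < B.N; ++i) {
          P(i, 0) = B.x[i]; P(i, 1) = B.y[i]; P(i, 2) = B.z[i];
          A(i, 0) = B.ax[i]; A(i, 1) = B.ay[i]; A(i, 2) = B.az[i];
        }
        configs[(R_xlen_t)i_cfg] = List::create(
          _["step"] = (double)step, _["positions"] = P, _["axes"] = A,
          _["N"] = B.N, _["E"] = E);
        ++i_cfg;
      }
    }
    if (dce > 0 && step % dce == 0) {
      bool ov = false;
      double Efull = B.total_energy(G, ev, ov);
      if (ov) stop("hard-core overlap detected during run at step %lld", step);
      double d = std::fabs(E - Efull) / std::max(1.0, std::fabs(Efull));
      if (d > max_drift) max_drift = d;
      E = Efull; // resynchronise after measuring drift
    }
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  bool ovf = false;
  double Efull = B.total_energy(G, ev, ovf);
  double final_drift = std::fabs(E - Efull) / std::max(1.0, std::fabs(Efull));
  if (final_drift > max_drift) max_drift = final_drift;

  NumericMatrix Pf(B.N, 3), Af(B.N, 3);
  for (int i = 0; i < B.N; ++i) {
    Pf(i, 0) = B.x[i]; Pf(i, 1) = B.y[i]; Pf(i, 2) = B.z[i];
    Af(i, 0) = B.ax[i]; Af(i, 1) = B.ay[i]; Af(i, 2) = B.az[i];
  }

  return List::create(
    _["records"] = records,
    _["configs"] = configs,
    _["final"] = List::create(_["positions"] = Pf, _["axes"] = Af,
                              _["N"] = B.N, _["E"] = Efull),
    _["counters"] = List::create(
      _["attempted"] = NumericVector::create(_["rt"] = att[0], _["insert"] = att[1], _["delete"] = att[2]),
      _["accepted"] = NumericVector::create(_["rt"] = acc[0], _["insert"] = acc[1], _["delete"] = acc[2])),
    _["max_drift"] = max_drift);
}

// --------------------------------------------------- bonding volume (MC)

// Orientation-averaged positional volume of the interaction shell in which
// a pair forms a geometric bond with negative energy. Radial sampling is
// r^3-uniform over [2 sigma_c, 2 sigma_c + delta] (uniform in shell
// volume); both axes are independent and uniform on the sphere.
// [[Rcpp::export(name = ".bonding_volume_cpp")]]
List bonding_volume_cpp(List geom, NumericVector eps, double n_samples) {
  Geom G = as_geom(geom);
  const double *ev = &eps[0];
  RNGScope scope;
  double r0 = G.r_core, r1 = G.r_cut;
  double c0 = r0 * r0 * r0, c1 = r1 * r1 * r1;
  long long n = (long long)n_samples, hits = 0;
  for (long long i = 0; i < n; ++i) {
    double r = std::cbrt(c0 + unif_rand() * (c1 - c0));
    double n1[3], n2[3];
    rand_axis(n1);
    rand_axis(n2);
    double u = pair_u(r, 0.0, 0.0, n1, n2, G, ev);
    if (u < 0.0) ++hits;
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  double p = (double)hits / (double)n;
  double Vshell = (4.0 * M_PI / 3.0) * (c1 - c0);
  double se = Vshell * std::sqrt(p * (1.0 - p) / (double)n);
  return List::create(_["V_b"] = Vshell * p, _["se"] = se,
                      _["p_bond"] = p, _["V_shell"] = Vshell,
                      _["n_samples"] = (double)n);
}

// ------------------------------------------- orientation-averaged Mayer f

// <exp(-beta U(r, Omega))>_Omega on a radial grid, by fixed-size Monte
// Carlo orientation sampling (two independent uniform axes per draw).
// Used by the second-virial quadrature and the two-particle detailed
// balance check.
// [[Rcpp::export(name = ".boltzmann_orient_avg_cpp")]]
NumericMatrix boltzmann_orient_avg_cpp(NumericVector r, double beta,
                                       List geom, NumericVector eps,
                                       double n_orient) {
  Geom G = as_geom(geom);
  const double *ev = &eps[0];
  RNGScope scope;
  int nr = r.size();
  long long no = (long long)n_orient;
  NumericMatrix out(nr, 2);
  for (int k = 0; k < nr; ++k) {
    double acc = 0.0, acc2 = 0.0;
    for (long long i = 0; i < no; ++i) {
      double n1[3], n2[3];
      rand_axis(n1);
      rand_axis(n2);
      double u = pair_u(r[k], 0.0, 0.0, n1, n2, G, ev);
      double b = (u == INF_E) ? 0.0 : std::exp(-beta * u);
      acc += b;
      acc2 += b * b;
    }
    double m = acc / (double)no;
    double v = acc2 / (double)no - m * m;
    if (v < 0) v = 0;
    out(k, 0) = m;
    out(k, 1) = std::sqrt(v / (double)no); // standard error of the mean
    Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("mean", "se");
  return out;
}

// ------------------------------------------------------------ bond tables

// all geometric bonds (2 sigma_c <= r <= 2 sigma_c + delta) of a periodic
// configuration, with pair energies; O(N^2), fine for snapshot analysis.
// [[Rcpp::export(name = ".bond_table_cpp")]]
NumericMatrix bond_table_cpp(NumericMatrix pos, NumericMatrix axes, double L,
                             List geom, NumericVector eps) {
  Geom G = as_geom(geom);
  const double *ev = &eps[0];
  int n = pos.nrow();
  std::vector<double> ii, jj, rr, uu;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0);
      double dy = pos(j, 1) - pos(i, 1);
      double dz = pos(j, 2) - pos(i, 2);
      dx -= L * std::round(dx / L);
      dy -= L * std::round(dy / L);
      dz -= L * std::round(dz / L);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > G.r_cut * G.r_cut) continue;
      double r = std::sqrt(d2);
      if (r < G.r_core - 1e-9) continue; // overlapping pairs are invalid, skip
      double n1[3] = {axes(i, 0), axes(i, 1), axes(i, 2)};
      double n2[3] = {axes(j, 0), axes(j, 1), axes(j, 2)};
      double u = pair_u(dx, dy, dz, n1, n2, G, ev);
      ii.push_back(i + 1); jj.push_back(j + 1); rr.push_back(r); uu.push_back(u);
    }
  }
  int m = (int)ii.size();
  NumericMatrix out(m, 4);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = ii[k]; out(k, 1) = jj[k]; out(k, 2) = rr[k]; out(k, 3) = uu[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "r", "energy");
  return out;
}
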