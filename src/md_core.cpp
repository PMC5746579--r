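// Compiled core of the coarse-grained microflow simulator.
//
// Reduced units throughout: epsilon = sigma = m = k_B = 1. The box is
// periodic in x and y only; z is bounded by frozen particle lattices plus
// soft containment planes (active only when frozen walls exist).
//
// Determinism contract: a private counter-free xoshiro256+ stream seeded by
// splitmix64 from the user seed; thermostat pairs are visited in sorted
// (i, j) index order with a single stream, so identical (state, seed) gives
// bit-identical trajectories on one platform.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0.0;
  // Marsaglia polar method; spare cached to keep draws cheap but ordered.
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// All pairs with centre distance < rc. Periodic in x,y only. Pairs are
// returned sorted by (i, j), i < j; pairs where both members are immobile
// are skipped when skip_frozen_pairs is set (they never move and the
// thermostat ignores them).
void build_pairs(const double* px, const double* py, const double* pz, int n,
                 double Lx, double Ly, double rc,
                 const int* mobile, bool skip_frozen_pairs,
                 std::vector<std::pair<int, int> >& out) {
  out.clear();
  const double rc2 = rc * rc;
  const int ncx = std::max(1, (int)std::floor(Lx / rc));
  const int ncy = std::max(1, (int)std::floor(Ly / rc));
  const bool brute = (n < 300) || ncx < 3 || ncy < 3;
  if (brute) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (skip_frozen_pairs && !mobile[i] && !mobile[j]) continue;
        const double dx = min_image(px[i] - px[j], Lx);
        const double dy = min_image(py[i] - py[j], Ly);
        const double dz = pz[i] - pz[j];
        if (dx * dx + dy * dy + dz * dz < rc2) out.emplace_back(i, j);
      }
    }
  } else {
    double zmin = pz[0], zmax = pz[0];
    for (int i = 1; i < n; ++i) {
      zmin = std::min(zmin, pz[i]);
      zmax = std::max(zmax, pz[i]);
    }
    const double zspan = std::max(zmax - zmin, rc);
    const int ncz = std::max(1, (int)std::floor(zspan / rc));
    const double cwx = Lx / ncx, cwy = Ly / ncy, cwz = zspan / ncz;
    std::vector<int> head(ncx * ncy * ncz, -1), nxt(n, -1);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      double x = px[i] - Lx * std::floor(px[i] / Lx);
      double y = py[i] - Ly * std::floor(py[i] / Ly);
      int a = std::min(ncx - 1, (int)(x / cwx));
      int b = std::min(ncy - 1, (int)(y / cwy));
      int c = std::min(ncz - 1, std::max(0, (int)((pz[i] - zmin) / cwz)));
      ci[i] = a; cj[i] = b; ck[i] = c;
      const int cell = (c * ncy + b) * ncx + a;
      nxt[i] = head[cell];
      head[cell] = i;
    }
    for (int i = 0; i < n; ++i) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int c = ck[i] + dc;
        if (c < 0 || c >= ncz) continue;
        for (int db = -1; db <= 1; ++db) {
          const int b = ((cj[i] + db) % ncy + ncy) % ncy;
          for (int da = -1; da <= 1; ++da) {
            const int a = ((ci[i] + da) % ncx + ncx) % ncx;
            for (int j = head[(c * ncy + b) * ncx + a]; j != -1; j = nxt[j]) {
              if (j <= i) continue;
              if (skip_frozen_pairs && !mobile[i] && !mobile[j]) continue;
              const double dx = min_image(px[i] - px[j], Lx);
              const double dy = min_image(py[i] - py[j], Ly);
              const double dz = pz[i] - pz[j];
              if (dx * dx + dy * dy + dz * dz < rc2) out.emplace_back(i, j);
            }
          }
        }
      }
    }
  }
  std::sort(out.begin(), out.end());
}

struct ForceParams {
  double Lx, Ly, Lz, rc, fx;
  bool contain;            // soft z planes, only when frozen walls exist
  double contain_k = 100.0;
  double hard_floor2 = 0.09;  // (0.3 sigma)^2: closer than this = blow-up
};

// WCA + harmonic bonds + core angle stiffening + tethers + body force.
// Returns false (and fills err) on a hard-floor overlap.
bool accumulate_forces(const double* px, const double* py, const double* pz,
                       int n, const std::vector<std::pair<int, int> >& pairs,
                       const int* solvent, const int* mobile,
                       const IntegerMatrix& bonds, const NumericVector& bond_r0,
                       const NumericVector& bond_k, const IntegerMatrix& angles,
                       const NumericVector& angle_k,
                       const IntegerVector& teth_idx, const NumericMatrix& teth_xyz,
                       const NumericVector& teth_k, const ForceParams& P,
                       double* fxv, double* fyv, double* fzv, std::string& err) {
  std::fill(fxv, fxv + n, 0.0);
  std::fill(fyv, fyv + n, 0.0);
  std::fill(fzv, fzv + n, 0.0);
  const double rw = std::min(P.rc, std::pow(2.0, 1.0 / 6.0));
  const double rw2 = rw * rw;
  for (size_t k = 0; k < pairs.size(); ++k) {
    const int i = pairs[k].first, j = pairs[k].second;
    const double dx = min_image(px[i] - px[j], P.Lx);
    const double dy = min_image(py[i] - py[j], P.Ly);
    const double dz = pz[i] - pz[j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < P.hard_floor2 && (mobile[i] || mobile[j])) {
      err = "particle overlap below hard floor (r = " +
            std::to_string(std::sqrt(r2)) + " sigma) between particles " +
            std::to_string(i + 1) + " and " + std::to_string(j + 1);
      return false;
    }
    if (r2 >= rw2) continue;
    const double inv2 = 1.0 / r2;
    const double s6 = inv2 * inv2 * inv2;
    const double fs = (48.0 * s6 * s6 - 24.0 * s6) * inv2;
    fxv[i] += dx * fs; fyv[i] += dy * fs; fzv[i] += dz * fs;
    fxv[j] -= dx * fs; fyv[j] -= dy * fs; fzv[j] -= dz * fs;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    const double dx = min_image(px[i] - px[j], P.Lx);
    const double dy = min_image(py[i] - py[j], P.Ly);
    const double dz = pz[i] - pz[j];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    const double fs = -bond_k[b] * (r - bond_r0[b]) / r;
    fxv[i] += dx * fs; fyv[i] += dy * fs; fzv[i] += dz * fs;
    fxv[j] -= dx * fs; fyv[j] -= dy * fs; fzv[j] -= dz * fs;
  }
  // E = k (1 + cos theta): minimum at the straight configuration.
  for (int a = 0; a < angles.nrow(); ++a) {
    const int i = angles(a, 0) - 1, j = angles(a, 1) - 1, l = angles(a, 2) - 1;
    const double ax = min_image(px[i] - px[j], P.Lx);
    const double ay = min_image(py[i] - py[j], P.Ly);
    const double az = pz[i] - pz[j];
    const double bx = min_image(px[l] - px[j], P.Lx);
    const double by = min_image(py[l] - py[j], P.Ly);
    const double bz = pz[l] - pz[j];
    const double na = std::sqrt(ax * ax + ay * ay + az * az);
    const double nb = std::sqrt(bx * bx + by * by + bz * bz);
    if (na < 1e-12 || nb < 1e-12) continue;
    const double ct = (ax * bx + ay * by + az * bz) / (na * nb);
    const double kk = angle_k[a];
    // F_i = -k d(cos theta)/d r_i
    const double fix = -kk * (bx / (na * nb) - ct * ax / (na * na));
    const double fiy = -kk * (by / (na * nb) - ct * ay / (na * na));
    const double fiz = -kk * (bz / (na * nb) - ct * az / (na * na));
    const double flx = -kk * (ax / (na * nb) - ct * bx / (nb * nb));
    const double fly = -kk * (ay / (na * nb) - ct * by / (nb * nb));
    const double flz = -kk * (az / (na * nb) - ct * bz / (nb * nb));
    fxv[i] += fix; fyv[i] += fiy; fzv[i] += fiz;
    fxv[l] += flx; fyv[l] += fly; fzv[l] += flz;
    fxv[j] -= (fix + flx); fyv[j] -= (fiy + fly); fzv[j] -= (fiz + flz);
  }
  for (int t = 0; t < teth_idx.size(); ++t) {
    const int i = teth_idx[t] - 1;
    fxv[i] -= teth_k[t] * (px[i] - teth_xyz(t, 0));
    fyv[i] -= teth_k[t] * (py[i] - teth_xyz(t, 1));
    fzv[i] -= teth_k[t] * (pz[i] - teth_xyz(t, 2));
  }
  for (int i = 0; i < n; ++i) {
    if (solvent[i] && mobile[i] && pz[i] > 0.0) fxv[i] += P.fx;
    if (P.contain && mobile[i]) {
      if (pz[i] < 0.0) fzv[i] += P.contain_k * (0.0 - pz[i]);
      if (pz[i] > P.Lz) fzv[i] += P.contain_k * (P.Lz - pz[i]);
    }
  }
  return true;
}

// One Lowe-Andersen sweep over mobile-mobile pairs within rc, sorted order.
void lowe_andersen_sweep(const std::vector<std::pair<int, int> >& pairs,
                         const double* px, const double* py, const double* pz,
                         double* vx, double* vy, double* vz,
                         const double* mass, const int* mobile,
                         double Lx, double Ly, double gamma_dt, double temp,
                         Xoshiro& rng) {
  for (size_t k = 0; k < pairs.size(); ++k) {
    const int i = pairs[k].first, j = pairs[k].second;
    if (!mobile[i] || !mobile[j]) continue;
    if (rng.unif() >= gamma_dt) continue;
    double ex = min_image(px[i] - px[j], Lx);
    double ey = min_image(py[i] - py[j], Ly);
    double ez = pz[i] - pz[j];
    const double r = std::sqrt(ex * ex + ey * ey + ez * ez);
    if (r < 1e-12) continue;
    ex /= r; ey /= r; ez /= r;
    const double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    const double vrel = (vx[i] - vx[j]) * ex + (vy[i] - vy[j]) * ey +
                        (vz[i] - vz[j]) * ez;
    const double vnew = std::sqrt(temp / mu) * rng.norm();
    const double d = vnew - vrel;
    vx[i] += (mu / mass[i]) * d * ex;
    vy[i] += (mu / mass[i]) * d * ey;
    vz[i] += (mu / mass[i]) * d * ez;
    vx[j] -= (mu / mass[j]) * d * ex;
    vy[j] -= (mu / mass[j]) * d * ey;
    vz[j] -= (mu / mass[j]) * d * ez;
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_compute_forces(NumericMatrix pos, IntegerVector solvent,
                                 IntegerVector mobile, IntegerMatrix bonds,
                                 NumericVector bond_r0, NumericVector bond_k,
                                 IntegerMatrix angles, NumericVector angle_k,
                                 IntegerVector teth_idx, NumericMatrix teth_xyz,
                                 NumericVector teth_k, NumericVector box,
                                 double fx, double rc, bool contain) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), fxv(n), fyv(n), fzv(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); }
  ForceParams P; P.Lx = box[0]; P.Ly = box[1]; P.Lz = box[2];
  P.rc = rc; P.fx = fx; P.contain = contain;
  std::vector<std::pair<int, int> > pairs;
  build_pairs(px.data(), py.data(), pz.data(), n, P.Lx, P.Ly, rc,
              INTEGER(mobile), false, pairs);
  std::string err;
  if (!accumulate_forces(px.data(), py.data(), pz.data(), n, pairs,
                         INTEGER(solvent), INTEGER(mobile), bonds, bond_r0,
                         bond_k, angles, angle_k, teth_idx, teth_xyz, teth_k,
                         P, fxv.data(), fyv.data(), fzv.data(), err))
    stop(err);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = fxv[i]; out(i, 1) = fyv[i]; out(i, 2) = fzv[i]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_lowe_andersen(NumericMatrix pos, NumericMatrix vel,
                                NumericVector mass, IntegerVector mobile,
                                NumericVector box, double rc, double gamma,
                                double dt, double temp, double seed) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  std::vector<std::pair<int, int> > pairs;
  build_pairs(px.data(), py.data(), pz.data(), n, box[0], box[1], rc,
              INTEGER(mobile), true, pairs);
  Xoshiro rng((uint64_t)seed);
  lowe_andersen_sweep(pairs, px.data(), py.data(), pz.data(),
                      vx.data(), vy.data(), vz.data(), REAL(mass),
                      INTEGER(mobile), box[0], box[1], gamma * dt, temp, rng);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = vx[i]; out(i, 1) = vy[i]; out(i, 2) = vz[i]; }
  return out;
}

// Integrate n_steps of velocity Verlet (+ optional thermostat), recording
// every record_every steps (plus the initial state). An equilibration
// segment of equil_steps with zero body force and thermostat on precedes
// production and is not recorded; production time starts at t0.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
             IntegerVector solvent, IntegerVector mobile, IntegerMatrix bonds,
             NumericVector bond_r0, NumericVector bond_k, IntegerMatrix angles,
             NumericVector angle_k, IntegerVector teth_idx,
             NumericMatrix teth_xyz, NumericVector teth_k, NumericVector box,
             double fx, double rc, double dt, double temp, double gamma,
             int n_steps, int record_every, int equil_steps, bool thermostat,
             bool contain, double seed, double t0) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  std::vector<double> fxa(n), fya(n), fza(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  const int* mob = INTEGER(mobile);
  const int* sol = INTEGER(solvent);
  const double* m = REAL(mass);
  ForceParams P; P.Lx = box[0]; P.Ly = box[1]; P.Lz = box[2];
  P.rc = rc; P.contain = contain;
  Xoshiro rng((uint64_t)seed);
  std::vector<std::pair<int, int> > pairs;
  std::string err;

  int n_mobile = 0, n_solv = 0;
  for (int i = 0; i < n; ++i) { if (mob[i]) ++n_mobile; if (sol[i] && mob[i]) ++n_solv; }

  const int n_rec = (record_every > 0 && n_steps > 0) ? n_steps / record_every : 0;
  List rec_pos(n_rec + 1), rec_vel(n_rec + 1);
  NumericVector rec_t(n_rec + 1), rec_vx(n_rec + 1), rec_T(n_rec + 1);
  int rec = 0;

  auto record = [&](double t) {
    NumericMatrix rp(n, 3), rv(n, 3);
    double sumvx = 0.0, ke = 0.0;
    for (int i = 0; i < n; ++i) {
      rp(i, 0) = px[i]; rp(i, 1) = py[i]; rp(i, 2) = pz[i];
      rv(i, 0) = vx[i]; rv(i, 1) = vy[i]; rv(i, 2) = vz[i];
      if (!std::isfinite(px[i]) || !std::isfinite(pz[i]))
        stop("non-finite coordinate at t = %f (particle %d)", t, i + 1);
      if (sol[i] && mob[i]) sumvx += vx[i];
      if (mob[i]) ke += m[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    rec_pos[rec] = rp; rec_vel[rec] = rv; rec_t[rec] = t;
    rec_vx[rec] = n_solv > 0 ? sumvx / n_solv : NA_REAL;
    rec_T[rec] = n_mobile > 0 ? ke / (3.0 * n_mobile) : NA_REAL;
    ++rec;
  };

  // soft start: during equilibration, cap per-particle net force so the
  // deterministic overlap-relaxed initial geometry cannot launch beads
  const double fcap = 50.0;
  auto cap_forces = [&]() {
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      const double fn = std::sqrt(fxa[i] * fxa[i] + fya[i] * fya[i] +
                                  fza[i] * fza[i]);
      if (fn > fcap) {
        const double sc = fcap / fn;
        fxa[i] *= sc; fya[i] *= sc; fza[i] *= sc;
      }
    }
  };

  auto one_step = [&](double body_fx, bool thermo, long step_index, bool cap) {
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      const double h = 0.5 * dt / m[i];
      vx[i] += h * fxa[i]; vy[i] += h * fya[i]; vz[i] += h * fza[i];
      px[i] += dt * vx[i]; py[i] += dt * vy[i]; pz[i] += dt * vz[i];
      px[i] -= P.Lx * std::floor(px[i] / P.Lx);
      py[i] -= P.Ly * std::floor(py[i] / P.Ly);
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
        stop("non-finite coordinate after step %ld (particle %d)", step_index, i + 1);
    }
    build_pairs(px.data(), py.data(), pz.data(), n, P.Lx, P.Ly, rc, mob, true, pairs);
    P.fx = body_fx;
    // while the soft-start cap is active a transient deep overlap is
    // recoverable, so the blow-up floor is only enforced in production
    P.hard_floor2 = cap ? 0.0 : 0.09;
    if (!accumulate_forces(px.data(), py.data(), pz.data(), n, pairs, sol, mob,
                           bonds, bond_r0, bond_k, angles, angle_k, teth_idx,
                           teth_xyz, teth_k, P,
                           fxa.data(), fya.data(), fza.data(), err))
      stop(err + " at step " + std::to_string(step_index));
    if (cap) cap_forces();
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      const double h = 0.5 * dt / m[i];
      vx[i] += h * fxa[i]; vy[i] += h * fya[i]; vz[i] += h * fza[i];
    }
    if (thermo && gamma > 0.0)
      lowe_andersen_sweep(pairs, px.data(), py.data(), pz.data(),
                          vx.data(), vy.data(), vz.data(), m, mob,
                          P.Lx, P.Ly, gamma * dt, temp, rng);
  };

  // initial forces (equilibration runs with zero body force)
  build_pairs(px.data(), py.data(), pz.data(), n, P.Lx, P.Ly, rc, mob, true, pairs);
  P.fx = equil_steps > 0 ? 0.0 : fx;
  P.hard_floor2 = equil_steps > 0 ? 0.0 : 0.09;
  if (!accumulate_forces(px.data(), py.data(), pz.data(), n, pairs, sol, mob,
                         bonds, bond_r0, bond_k, angles, angle_k, teth_idx,
                         teth_xyz, teth_k, P,
                         fxa.data(), fya.data(), fza.data(), err))
    stop(err + " in initial state");
  if (equil_steps > 0) cap_forces();

  for (long s = 0; s < equil_steps; ++s) {
    one_step(0.0, thermostat, s - equil_steps, true);
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (equil_steps > 0) {
    // refresh forces with the production body force before recording t0
    build_pairs(px.data(), py.data(), pz.data(), n, P.Lx, P.Ly, rc, mob, true, pairs);
    P.fx = fx;
    accumulate_forces(px.data(), py.data(), pz.data(), n, pairs, sol, mob,
                      bonds, bond_r0, bond_k, angles, angle_k, teth_idx,
                      teth_xyz, teth_k, P, fxa.data(), fya.data(), fza.data(), err);
  }
  record(t0);
  for (long s = 1; s <= n_steps; ++s) {
    one_step(fx, thermostat, s, false);
    if (record_every > 0 && s % record_every == 0) record(t0 + s * dt);
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = rec_t, _["positions"] = rec_pos,
                      _["velocities"] = rec_vel, _["mean_vx"] = rec_vx,
                      _["kinetic_T"] = rec_T);
}

// Random sequential insertion of n points in [0,Lx)x[0,Ly)x[zlo,zhi] with
// minimum pairwise distance mindist to each other and to `existing`.
// [[Rcpp::export]]
NumericMatrix cpp_place_solvent(int n, NumericVector box, double zlo,
                                double zhi, NumericMatrix existing,
                                double mindist, double seed, int max_tries) {
  const double Lx = box[0], Ly = box[1];
  const double md2 = mindist * mindist;
  Xoshiro rng((uint64_t)seed);
  const int ncx = std::max(1, (int)std::floor(Lx / mindist));
  const int ncy = std::max(1, (int)std::floor(Ly / mindist));
  const int ncz = std::max(1, (int)std::floor((zhi - zlo) / mindist));
  std::vector<std::vector<int> > cells(ncx * ncy * ncz);
  std::vector<double> X, Y, Z;
  X.reserve(n + existing.nrow());
  auto cell_of = [&](double x, double y, double z) {
    int a = std::min(ncx - 1, std::max(0, (int)(x / (Lx / ncx))));
    int b = std::min(ncy - 1, std::max(0, (int)(y / (Ly / ncy))));
    int c = std::min(ncz - 1, std::max(0, (int)((z - zlo) / ((zhi - zlo) / ncz))));
    return (c * ncy + b) * ncx + a;
  };
  auto clash = [&](double x, double y, double z) {
    int a0 = (int)(x / (Lx / ncx)), b0 = (int)(y / (Ly / ncy));
    int c0 = (int)((z - zlo) / ((zhi - zlo) / ncz));
    for (int dc = -1; dc <= 1; ++dc) {
      int c = c0 + dc;
      if (c < 0 || c >= ncz) continue;
      for (int db = -1; db <= 1; ++db) {
        int b = ((b0 + db) % ncy + ncy) % ncy;
        for (int da = -1; da <= 1; ++da) {
          int a = ((a0 + da) % ncx + ncx) % ncx;
          const std::vector<int>& cell = cells[(c * ncy + b) * ncx + a];
          for (size_t k = 0; k < cell.size(); ++k) {
            const int i = cell[k];
            const double dx = min_image(x - X[i], Lx);
            const double dy = min_image(y - Y[i], Ly);
            const double dz = z - Z[i];
            if (dx * dx + dy * dy + dz * dz < md2) return true;
          }
        }
      }
    }
    return false;
  };
  for (int i = 0; i < existing.nrow(); ++i) {
    double x = existing(i, 0) - Lx * std::floor(existing(i, 0) / Lx);
    double y = existing(i, 1) - Ly * std::floor(existing(i, 1) / Ly);
    double z = existing(i, 2);
    X.push_back(x); Y.push_back(y); Z.push_back(z);
    if (z >= zlo - mindist && z <= zhi + mindist)
      cells[cell_of(x, y, std::min(std::max(z, zlo), zhi))].push_back((int)X.size() - 1);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      const double x = rng.unif() * Lx;
      const double y = rng.unif() * Ly;
      const double z = zlo + rng.unif() * (zhi - zlo);
      if (clash(x, y, z)) continue;
      X.push_back(x); Y.push_back(y); Z.push_back(z);
      cells[cell_of(x, y, z)].push_back((int)X.size() - 1);
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
      placed = true;
      break;
    }
    if (!placed) {
      const double vol = Lx * Ly * (zhi - zlo);
      stop("solvent packing failed after %d tries at particle %d of %d "
           "(achieved number density %.3f per sigma^3)",
           max_tries, i + 1, n, i / vol);
    }
  }
  return out;
}
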