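// Rigid-body Langevin dynamics for tetrahedral patchy spheres.
//
// Pair energy (reduced units, sigma = centre-centre contact distance = 1):
//   U(r, Omega_i, Omega_j) = U_body(r) + U_patch(r) * f_i * f_j
// with U_body/U_patch the 2n-n Lennard-Jones form 4 eps [ (s/r)^2n - (s/r)^n ],
// n = 24, and f = exp(-theta^2 / (2 delta^2)) the Gaussian alignment factor of
// the best-aligned patch axis against the centre line (continuous
// Kern-Frenkel-style modulation). Bottom (and top) wall: WCA. Gravity: g*z.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct PModel {
  double sigma, eps_p, eps_b, eps_w, delta, g, rcut, mass, inertia;
  int n;
  int body_wca;  // 1: body channel is repulsive-only (WCA form), 0: full LJ
  double patch[4][3];
  int npatch;
};

static inline double mind(double d, double L, bool per) {
  if (per) d -= L * std::round(d / L);
  return d;
}

static inline void quat_rot(const double *q, const double *v, double *out) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double tx = 2 * (y * v[2] - z * v[1]);
  double ty = 2 * (z * v[0] - x * v[2]);
  double tz = 2 * (x * v[1] - y * v[0]);
  out[0] = v[0] + w * tx + (y * tz - z * ty);
  out[1] = v[1] + w * ty + (z * tx - x * tz);
  out[2] = v[2] + w * tz + (x * ty - y * tx);
}

// (s/r)^n and (s/r)^2n, fast path n = 24
static inline void ljpow(double inv2, int n, double &sn, double &s2n) {
  if (n == 24) {
    double s6 = inv2 * inv2 * inv2;       // (s/r)^6
    double s12 = s6 * s6;
    sn = s12 * s12;
    s2n = sn * sn;
  } else {
    sn = std::pow(inv2, n / 2.0);
    s2n = sn * sn;
  }
}

static PModel model_from_list(List m) {
  PModel pm;
  pm.sigma = as<double>(m["sigma"]);
  pm.n = as<int>(m["n_exp"]);
  pm.eps_p = as<double>(m["eps_patch"]);
  pm.eps_b = as<double>(m["eps_body"]);
  pm.eps_w = as<double>(m["eps_wca"]);
  pm.delta = as<double>(m["patch_halfwidth_rad"]);
  pm.g = as<double>(m["gravity"]);
  pm.rcut = as<double>(m["rcut"]);
  pm.body_wca = as<int>(m["body_wca"]);
  pm.mass = as<double>(m["mass"]);
  pm.inertia = as<double>(m["inertia"]);
  NumericMatrix pa = m["patch_axes"];
  pm.npatch = pa.nrow();
  if (pm.npatch > 4) stop("at most 4 patch axes supported");
  for (int a = 0; a < pm.npatch; ++a)
    for (int k = 0; k < 3; ++k) pm.patch[a][k] = pa(a, k);
  return pm;
}

// Energy/forces/torques over all pairs + wall + gravity.
// pos: N x 3, quat: N x 4. Returns potential energy; fills F (N x 3), T (N x 3).
static double compute_forces(const std::vector<double> &pos,
                             const std::vector<double> &quat, int N,
                             const PModel &pm, const double *box,
                             const bool *per, bool wall,
                             std::vector<double> &F, std::vector<double> &T,
                             double *e_pair, double *e_grav, double *e_wall) {
  std::fill(F.begin(), F.end(), 0.0);
  std::fill(T.begin(), T.end(), 0.0);
  double Upair = 0, Ugrav = 0, Uwall = 0;
  const double rc2 = pm.rcut * pm.rcut;
  const double d2 = pm.delta * pm.delta;

  // rotated patch axes, cached per particle
  std::vector<double> pax((size_t)N * pm.npatch * 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < pm.npatch; ++a)
      quat_rot(&quat[4 * i], pm.patch[a], &pax[(((size_t)i * pm.npatch) + a) * 3]);

  // cell list (rebuilt every call)
  int nc[3];
  for (int a = 0; a < 3; ++a) {
    nc[a] = std::max(1, (int)std::floor(box[a] / pm.rcut));
    if (per[a] && nc[a] < 3) nc[a] = 1;  // degenerate: single cell, all pairs
  }
  long ntot = (long)nc[0] * nc[1] * nc[2];
  std::vector<int> head(ntot, -1), nxt(N, -1);
  for (int i = 0; i < N; ++i) {
    int c[3];
    for (int a = 0; a < 3; ++a) {
      double x = pos[3 * i + a];
      if (per[a]) x -= box[a] * std::floor(x / box[a]);
      int k = (int)std::floor(x / box[a] * nc[a]);
      c[a] = std::min(std::max(k, 0), nc[a] - 1);
    }
    int idx = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    nxt[i] = head[idx];
    head[idx] = i;
  }

  auto do_pair = [&](int i, int j) {
    double dx = mind(pos[3*j]   - pos[3*i],   box[0], per[0]);
    double dy = mind(pos[3*j+1] - pos[3*i+1], box[1], per[1]);
    double dz = mind(pos[3*j+2] - pos[3*i+2], box[2], per[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2 || r2 <= 0) return;
    double r = std::sqrt(r2);
    double inv2 = pm.sigma * pm.sigma / r2;
    double sn, s2n;
    ljpow(inv2, pm.n, sn, s2n);
    double ub, dub;
    if (pm.body_wca) {
      // repulsive-only body channel: truncated-shifted at the minimum
      double rcw = pm.sigma * std::pow(2.0, 1.0 / pm.n);
      if (r < rcw) {
        ub = 4 * pm.eps_b * (s2n - sn + 0.25);
        dub = 4 * pm.eps_b * pm.n * (sn - 2 * s2n) / r;
      } else { ub = 0; dub = 0; }
    } else {
      ub = 4 * pm.eps_b * (s2n - sn);
      dub = 4 * pm.eps_b * pm.n * (sn - 2 * s2n) / r;   // dU/dr
    }
    double up = 4 * pm.eps_p * (s2n - sn);
    double dup = 4 * pm.eps_p * pm.n * (sn - 2 * s2n) / r;
    double u[3] = {dx / r, dy / r, dz / r};
    // best-aligned patch of i along +u, of j along -u
    int bi = 0, bj = 0;
    double ci = -2, cj = -2;
    for (int a = 0; a < pm.npatch; ++a) {
      const double *p = &pax[(((size_t)i * pm.npatch) + a) * 3];
      double c = p[0] * u[0] + p[1] * u[1] + p[2] * u[2];
      if (c > ci) { ci = c; bi = a; }
      const double *q = &pax[(((size_t)j * pm.npatch) + a) * 3];
      double cc = -(q[0] * u[0] + q[1] * u[1] + q[2] * u[2]);
      if (cc > cj) { cj = cc; bj = a; }
    }
    ci = std::min(1.0, std::max(-1.0, ci));
    cj = std::min(1.0, std::max(-1.0, cj));
    double thi = std::acos(ci), thj = std::acos(cj);
    double fi = std::exp(-thi * thi / (2 * d2));
    double fj = std::exp(-thj * thj / (2 * d2));
    Upair += ub + up * fi * fj;
    // radial force on j along +u
    double frad = -(dub + dup * fi * fj);
    // dF/dc factors: df/dc = f * theta / (delta^2 sin(theta)); theta->0 limit f/delta^2
    double si = std::sin(thi), sj = std::sin(thj);
    double gi = (si < 1e-8) ? fi / d2 : fi * thi / (d2 * si);
    double gj = (sj < 1e-8) ? fj / d2 : fj * thj / (d2 * sj);
    const double *Pi = &pax[(((size_t)i * pm.npatch) + bi) * 3];
    const double *Pj = &pax[(((size_t)j * pm.npatch) + bj) * 3];
    // grad_{x_j} ci = (Pi - ci u)/r ; grad_{x_j} cj = -(Pj + cj u)/r
    double Fj[3];
    for (int k = 0; k < 3; ++k) {
      double gci = (Pi[k] - ci * u[k]) / r;
      double gcj = -(Pj[k] + cj * u[k]) / r;
      Fj[k] = frad * u[k] - up * (fj * gi * gci + fi * gj * gcj);
    }
    for (int k = 0; k < 3; ++k) {
      F[3 * j + k] += Fj[k];
      F[3 * i + k] -= Fj[k];
    }
    // torques: tau_i = -up*fj*gi*(Pi x u); tau_j = +up*fi*gj*(Pj x u)
    double cx_i[3] = {Pi[1] * u[2] - Pi[2] * u[1], Pi[2] * u[0] - Pi[0] * u[2],
                      Pi[0] * u[1] - Pi[1] * u[0]};
    double cx_j[3] = {Pj[1] * u[2] - Pj[2] * u[1], Pj[2] * u[0] - Pj[0] * u[2],
                      Pj[0] * u[1] - Pj[1] * u[0]};
    for (int k = 0; k < 3; ++k) {
      T[3 * i + k] += -up * fj * gi * cx_i[k];
      T[3 * j + k] += up * fi * gj * cx_j[k];
    }
  };

  if (ntot <= 2) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) do_pair(i, j);
  } else {
    int nbr[27];
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c0 = (cz * nc[1] + cy) * nc[0] + cx;
          int nn = 0;
          for (int dz3 = -1; dz3 <= 1; ++dz3)
            for (int dy3 = -1; dy3 <= 1; ++dy3)
              for (int dx3 = -1; dx3 <= 1; ++dx3) {
                int ex = cx + dx3, ey = cy + dy3, ez = cz + dz3;
                if (per[0]) ex = (ex + nc[0]) % nc[0];
                if (per[1]) ey = (ey + nc[1]) % nc[1];
                if (per[2]) ez = (ez + nc[2]) % nc[2];
                if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
                    ez < 0 || ez >= nc[2]) continue;
                nbr[nn++] = (ez * nc[1] + ey) * nc[0] + ex;
              }
          std::sort(nbr, nbr + nn);
          nn = (int)(std::unique(nbr, nbr + nn) - nbr);
          for (int t = 0; t < nn; ++t) {
            int c1 = nbr[t];
            if (c1 < c0) continue;
            for (int i = head[c0]; i != -1; i = nxt[i])
              for (int j = (c1 == c0 ? nxt[i] : head[c1]); j != -1; j = nxt[j])
                do_pair(std::min(i, j), std::max(i, j));
          }
        }
  }

  // gravity + walls (z axis)
  const double wsig = 0.5 * pm.sigma;           // wall contact length
  const double wcut = wsig * std::pow(2.0, 1.0 / pm.n);
  for (int i = 0; i < N; ++i) {
    double z = pos[3 * i + 2];
    if (pm.g != 0) { Ugrav += pm.g * z; F[3 * i + 2] -= pm.g; }
    if (wall) {
      if (z < wcut && z > 0) {
        double inv2 = wsig * wsig / (z * z);
        double sn, s2n;
        ljpow(inv2, pm.n, sn, s2n);
        Uwall += 4 * pm.eps_w * (s2n - sn + 0.25);
        F[3 * i + 2] -= 4 * pm.eps_w * pm.n * (sn - 2 * s2n) / z;
      }
      double zt = box[2] - z;
      if (zt < wcut && zt > 0) {
        double inv2 = wsig * wsig / (zt * zt);
        double sn, s2n;
        ljpow(inv2, pm.n, sn, s2n);
        Uwall += 4 * pm.eps_w * (s2n - sn + 0.25);
        F[3 * i + 2] += 4 * pm.eps_w * pm.n * (sn - 2 * s2n) / zt;
      }
    }
  }
  if (e_pair) *e_pair = Upair;
  if (e_grav) *e_grav = Ugrav;
  if (e_wall) *e_wall = Uwall;
  return Upair + Ugrav + Uwall;
}

// [[Rcpp::export]]
List cpp_patchy_forces(NumericMatrix pos, NumericMatrix quat, List model,
                       NumericVector box, LogicalVector periodic, bool wall) {
  int N = pos.nrow();
  PModel pm = model_from_list(model);
  std::vector<double> P(3 * N), Q(4 * N), F(3 * N), T(3 * N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) P[3 * i + k] = pos(i, k);
    for (int k = 0; k < 4; ++k) Q[4 * i + k] = quat(i, k);
  }
  double bx[3] = {box[0], box[1], box[2]};
  bool per[3] = {(bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  double ep, eg, ew;
  double U = compute_forces(P, Q, N, pm, bx, per, wall, F, T, &ep, &eg, &ew);
  NumericMatrix Fo(N, 3), To(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { Fo(i, k) = F[3*i+k]; To(i, k) = T[3*i+k]; }
  return List::create(_["energy"] = U, _["e_pair"] = ep, _["e_gravity"] = eg,
                      _["e_wall"] = ew, _["forces"] = Fo, _["torques"] = To);
}

struct RNG {
  std::uint64_t s;
  bool has_spare = false;
  double spare = 0;
  explicit RNG(std::uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  double unif() {  // splitmix64
    s += 0x9e3779b97f4a7c15ULL;
    std::uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2 * M_PI * u2);
    has_spare = true;
    return m * std::cos(2 * M_PI * u2);
  }
};

static inline void quat_step(double *q, const double *w, double dt) {
  double wn = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  if (wn < 1e-14) return;
  double half = 0.5 * wn * dt;
  double cw = std::cos(half), sw = std::sin(half) / wn;
  double dq[4] = {cw, sw * w[0], sw * w[1], sw * w[2]};
  double r[4] = {
    dq[0]*q[0] - dq[1]*q[1] - dq[2]*q[2] - dq[3]*q[3],
    dq[0]*q[1] + dq[1]*q[0] + dq[2]*q[3] - dq[3]*q[2],
    dq[0]*q[2] - dq[1]*q[3] + dq[2]*q[0] + dq[3]*q[1],
    dq[0]*q[3] + dq[1]*q[2] - dq[2]*q[1] + dq[3]*q[0]};
  double n = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2] + r[3]*r[3]);
  for (int k = 0; k < 4; ++k) q[k] = r[k] / n;
}

// BAOAB Langevin integrator (translations) + rotational analogue for
// isotropic-inertia rigid spheres. gamma = 0 gives microcanonical (NVE)
// velocity-Verlet dynamics, used by the energy-conservation precondition.
// [[Rcpp::export]]
List cpp_patchy_run(NumericMatrix pos, NumericMatrix quat, NumericMatrix vel,
                    NumericMatrix angvel, List model, NumericVector box,
                    LogicalVector periodic, bool wall, double dt, int steps,
                    double gamma_t, double gamma_r, double temperature,
                    double seed, int stride, int energy_stride) {
  int N = pos.nrow();
  PModel pm = model_from_list(model);
  std::vector<double> P(3*N), Q(4*N), V(3*N), W(3*N), F(3*N), T(3*N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) {
      P[3*i+k] = pos(i,k); V[3*i+k] = vel(i,k); W[3*i+k] = angvel(i,k);
    }
    for (int k = 0; k < 4; ++k) Q[4*i+k] = quat(i,k);
  }
  double bx[3] = {box[0], box[1], box[2]};
  bool per[3] = {(bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  RNG rng((std::uint64_t)seed);
  const double m = pm.mass, I = pm.inertia;
  const double c1t = (gamma_t > 0) ? std::exp(-gamma_t * dt) : 1.0;
  const double c2t = (gamma_t > 0) ? std::sqrt(temperature * (1 - c1t*c1t) / m) : 0.0;
  const double c1r = (gamma_r > 0) ? std::exp(-gamma_r * dt) : 1.0;
  const double c2r = (gamma_r > 0) ? std::sqrt(temperature * (1 - c1r*c1r) / I) : 0.0;

  double ep, eg, ew;
  double U = compute_forces(P, Q, N, pm, bx, per, wall, F, T, &ep, &eg, &ew);

  List snaps;
  std::vector<double> et_time, et_pot, et_kin;
  auto record_energy = [&](int step, double Ucur) {
    double KE = 0;
    for (int i = 0; i < 3 * N; ++i)
      KE += 0.5 * m * V[i] * V[i] + 0.5 * I * W[i] * W[i];
    et_time.push_back(step * dt);
    et_pot.push_back(Ucur);
    et_kin.push_back(KE);
  };
  record_energy(0, U);

  for (int step = 1; step <= steps; ++step) {
    // B
    for (int i = 0; i < 3*N; ++i) { V[i] += 0.5*dt*F[i]/m; W[i] += 0.5*dt*T[i]/I; }
    // A
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < 3; ++k) P[3*i+k] += 0.5*dt*V[3*i+k];
      quat_step(&Q[4*i], &W[3*i], 0.5*dt);
    }
    // O
    if (gamma_t > 0 || gamma_r > 0) {
      for (int i = 0; i < 3*N; ++i) {
        V[i] = c1t * V[i] + c2t * rng.norm();
        W[i] = c1r * W[i] + c2r * rng.norm();
      }
    }
    // A
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < 3; ++k) P[3*i+k] += 0.5*dt*V[3*i+k];
      quat_step(&Q[4*i], &W[3*i], 0.5*dt);
    }
    // wrap periodic axes; reflect at walls (the WCA wall is steep enough that
    // reflections are rare, but they guarantee impenetrability at finite dt)
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) {
        if (per[k]) {
          P[3*i+k] -= bx[k] * std::floor(P[3*i+k] / bx[k]);
        } else if (wall && k == 2) {
          if (P[3*i+k] < 0) { P[3*i+k] = -P[3*i+k]; V[3*i+k] = -V[3*i+k]; }
          if (P[3*i+k] > bx[k]) {
            P[3*i+k] = 2 * bx[k] - P[3*i+k];
            V[3*i+k] = -V[3*i+k];
          }
        }
      }
    U = compute_forces(P, Q, N, pm, bx, per, wall, F, T, &ep, &eg, &ew);
    // B
    for (int i = 0; i < 3*N; ++i) { V[i] += 0.5*dt*F[i]/m; W[i] += 0.5*dt*T[i]/I; }

    if (!std::isfinite(U)) stop("instability: non-finite energy at step %d", step);
    if (step % 50 == 0) {
      double v2max = 0;
      for (int i = 0; i < 3 * N; ++i) v2max = std::max(v2max, V[i] * V[i]);
      if (v2max > 4e4)  // |v| > 200 sigma/tau: integration has blown up
        stop("instability: runaway velocity (|v| = %.3g) at step %d; reduce dt",
             std::sqrt(v2max), step);
    }
    if (energy_stride > 0 && step % energy_stride == 0) record_energy(step, U);
    if (stride > 0 && step % stride == 0) {
      NumericMatrix sp(N, 3), sq(N, 4);
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < 3; ++k) sp(i, k) = P[3*i+k];
        for (int k = 0; k < 4; ++k) sq(i, k) = Q[4*i+k];
      }
      snaps.push_back(List::create(_["step"] = step, _["pos"] = sp, _["quat"] = sq));
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix sp(N, 3), sq(N, 4), sv(N, 3), sw(N, 3);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) { sp(i,k)=P[3*i+k]; sv(i,k)=V[3*i+k]; sw(i,k)=W[3*i+k]; }
    for (int k = 0; k < 4; ++k) sq(i, k) = Q[4*i+k];
  }
  return List::create(
      _["pos"] = sp, _["quat"] = sq, _["vel"] = sv, _["angvel"] = sw,
      _["energy"] = U, _["snapshots"] = snaps,
      _["energy_series"] = DataFrame::create(_["time"] = et_time,
                                             _["potential"] = et_pot,
                                             _["kinetic"] = et_kin));
}
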