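// Growth-and-quench jamming of frictionless soft spheres in a periodic unit
// box. Harmonic overlap energy U = sum (1/2)(1 - d/s_ij)^2 for d < s_ij is
// minimized with FIRE after each growth step; the packing fraction is bisected
// until the residual energy per particle sits in a narrow just-jammed window.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cells {
  int nc[3];
  std::vector<int> head, nxt;
};

inline double pim(double d) { return d - std::round(d); }  // unit box

void build_cells(const std::vector<double> &P, int N, double cut, Cells &cl) {
  for (int a = 0; a < 3; ++a) cl.nc[a] = std::max(3, (int)std::floor(1.0 / cut));
  long ntot = (long)cl.nc[0] * cl.nc[1] * cl.nc[2];
  cl.head.assign(ntot, -1);
  cl.nxt.assign(N, -1);
  for (int i = 0; i < N; ++i) {
    int c[3];
    for (int a = 0; a < 3; ++a) {
      double x = P[3 * i + a];
      x -= std::floor(x);
      int k = (int)(x * cl.nc[a]);
      c[a] = std::min(std::max(k, 0), cl.nc[a] - 1);
    }
    int idx = (c[2] * cl.nc[1] + c[1]) * cl.nc[0] + c[0];
    cl.nxt[i] = cl.head[idx];
    cl.head[idx] = i;
  }
}

// energy + forces; returns E. Radii in box units.
double eval(const std::vector<double> &P, const std::vector<double> &R, int N,
            std::vector<double> &F, const Cells &cl) {
  std::fill(F.begin(), F.end(), 0.0);
  double E = 0;
  const int *nc = cl.nc;
  int nbr[27];
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int c0 = (cz * nc[1] + cy) * nc[0] + cx;
        int nn = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = (cx + dx + nc[0]) % nc[0];
              int ey = (cy + dy + nc[1]) % nc[1];
              int ez = (cz + dz + nc[2]) % nc[2];
              nbr[nn++] = (ez * nc[1] + ey) * nc[0] + ex;
            }
        std::sort(nbr, nbr + nn);
        nn = (int)(std::unique(nbr, nbr + nn) - nbr);
        for (int t = 0; t < nn; ++t) {
          int c1 = nbr[t];
          if (c1 < c0) continue;
          for (int i = cl.head[c0]; i != -1; i = cl.nxt[i])
            for (int j = (c1 == c0 ? cl.nxt[i] : cl.head[c1]); j != -1; j = cl.nxt[j]) {
              double dx = pim(P[3*j]   - P[3*i]);
              double dy = pim(P[3*j+1] - P[3*i+1]);
              double dz = pim(P[3*j+2] - P[3*i+2]);
              double s = R[i] + R[j];
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 >= s * s || d2 <= 0) continue;
              double d = std::sqrt(d2);
              double ov = 1.0 - d / s;
              E += 0.5 * ov * ov;
              double fmag = ov / (s * d);  // dU/dd = -ov/s; F along +u on j
              F[3*j]   += fmag * dx;
              F[3*j+1] += fmag * dy;
              F[3*j+2] += fmag * dz;
              F[3*i]   -= fmag * dx;
              F[3*i+1] -= fmag * dy;
              F[3*i+2] -= fmag * dz;
            }
        }
      }
  return E;
}

// FIRE minimization; returns final energy, iterations via *iters.
double fire(std::vector<double> &P, const std::vector<double> &R, int N,
            double ftol, double e_floor, int maxit, int *iters) {
  std::vector<double> V(3 * N, 0.0), F(3 * N);
  double rmax = *std::max_element(R.begin(), R.end());
  double cut = 2 * rmax * 1.0001;
  Cells cl;
  build_cells(P, N, cut, cl);
  double E = eval(P, R, N, F, cl);
  double dt = 0.1 * rmax, dtmax = 1.0 * rmax, alpha = 0.1;
  int npos = 0, it = 0;
  int rebuild = 0;
  for (it = 0; it < maxit; ++it) {
    double p = 0, vn = 0, fn = 0, fmax = 0;
    for (int k = 0; k < 3 * N; ++k) {
      p += V[k] * F[k];
      vn += V[k] * V[k];
      fn += F[k] * F[k];
    }
    for (int i = 0; i < N; ++i) {
      double f2 = F[3*i]*F[3*i] + F[3*i+1]*F[3*i+1] + F[3*i+2]*F[3*i+2];
      fmax = std::max(fmax, f2);
    }
    fmax = std::sqrt(fmax);
    if (fmax < ftol || E / N < e_floor) break;
    if (p > 0) {
      ++npos;
      if (npos > 5) { dt = std::min(dt * 1.1, dtmax); alpha *= 0.99; }
      double mix = (fn > 0) ? alpha * std::sqrt(vn / fn) : 0;
      for (int k = 0; k < 3 * N; ++k) V[k] = (1 - alpha) * V[k] + mix * F[k];
    } else {
      npos = 0;
      dt *= 0.5;
      alpha = 0.1;
      std::fill(V.begin(), V.end(), 0.0);
    }
    for (int k = 0; k < 3 * N; ++k) {
      V[k] += dt * F[k];
      P[k] += dt * V[k];
    }
    for (int k = 0; k < 3 * N; ++k) P[k] -= std::floor(P[k]);
    if (++rebuild >= 8) { build_cells(P, N, cut, cl); rebuild = 0; }
    else build_cells(P, N, cut, cl);  // cheap; rebuild every step for correctness
    E = eval(P, R, N, F, cl);
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  *iters = it;
  return E;
}

}  // namespace

// [[Rcpp::export]]
List cpp_jam(NumericMatrix pos0, NumericVector rel_radii, double phi_start,
             double dphi_start, double e_lo, double e_hi, double ftol,
             int max_fire, int max_outer) {
  int N = pos0.nrow();
  std::vector<double> P(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = pos0(i, k);
  double sum3 = 0;
  for (int i = 0; i < N; ++i) sum3 += std::pow(rel_radii[i], 3.0);
  auto scale_for = [&](double phi) {
    return std::cbrt(3.0 * phi / (4.0 * M_PI * sum3));
  };
  std::vector<double> R(N);
  double phi = phi_start, dphi = dphi_start;
  double e_floor = e_lo * 1e-4;
  int total_it = 0, outer = 0;
  bool jammed_window = false;
  double E = 0;
  for (outer = 0; outer < max_outer; ++outer) {
    double s = scale_for(phi);
    for (int i = 0; i < N; ++i) R[i] = rel_radii[i] * s;
    int it = 0;
    E = fire(P, R, N, ftol, e_floor, max_fire, &it);
    total_it += it;
    double epp = E / N;
    if (epp > e_hi) {        // overcompressed: back off, refine
      phi -= dphi;
      dphi *= 0.5;
      phi += dphi;
    } else if (epp < e_lo) { // unjammed (or barely): grow
      phi += dphi;
    } else {
      jammed_window = true;
      break;
    }
    if (dphi < 1e-7) break;
  }
  if (!jammed_window) {
    return List::create(_["converged"] = false, _["phi"] = phi,
                        _["energy_per_particle"] = E / N,
                        _["pos"] = pos0, _["outer_iterations"] = outer,
                        _["fire_iterations"] = total_it);
  }
  double s = scale_for(phi);
  NumericMatrix Pout(N, 3);
  NumericVector Rout(N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) Pout(i, k) = P[3 * i + k];
    Rout[i] = rel_radii[i] * s;
  }
  return List::create(_["converged"] = true, _["phi"] = phi, _["pos"] = Pout,
                      _["radii"] = Rout, _["energy_per_particle"] = E / N,
                      _["outer_iterations"] = outer,
                      _["fire_iterations"] = total_it);
}
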