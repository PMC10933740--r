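#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double mindelta(double d, double L, bool per) {
  if (per) d -= L * std::round(d / L);
  return d;
}

// Pair list under the distance criterion d_ij <= r_i + r_j + gap.
// Cell lists when the box admits >= 3 cells per periodic axis, else brute force.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, NumericVector radii,
                                NumericVector box, LogicalVector periodic,
                                double gap) {
  const int N = pos.nrow();
  double rmax = 0.0;
  for (int i = 0; i < N; ++i) rmax = std::max(rmax, radii[i]);
  const double cut = 2.0 * rmax + gap;

  std::vector<int> pi, pj;
  pi.reserve(8 * N);
  pj.reserve(8 * N);

  int nc[3];
  bool cells_ok = true;
  for (int a = 0; a < 3; ++a) {
    nc[a] = (int)std::floor(box[a] / cut);
    if (nc[a] < 1) nc[a] = 1;
    if (periodic[a] && nc[a] < 3) cells_ok = false;
    if (!periodic[a] && nc[a] < 1) cells_ok = false;
  }
  long ncell_tot = (long)nc[0] * nc[1] * nc[2];
  if (ncell_tot > 8L * (N + 64L)) {
    // avoid huge sparse cell grids; shrink proportionally
    double f = std::cbrt((double)ncell_tot / (8.0 * (N + 64)));
    for (int a = 0; a < 3; ++a) nc[a] = std::max(1, (int)(nc[a] / f));
    for (int a = 0; a < 3; ++a)
      if (periodic[a] && nc[a] < 3) cells_ok = false;
  }

  if (!cells_ok || N < 200) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = mindelta(pos(j,0) - pos(i,0), box[0], periodic[0]);
        double dy = mindelta(pos(j,1) - pos(i,1), box[1], periodic[1]);
        double dz = mindelta(pos(j,2) - pos(i,2), box[2], periodic[2]);
        double d2 = dx*dx + dy*dy + dz*dz;
        double c = radii[i] + radii[j] + gap;
        if (d2 <= c * c) { pi.push_back(i + 1); pj.push_back(j + 1); }
      }
  } else {
    ncell_tot = (long)nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell_tot, -1), nxt(N, -1), cellof(N);
    for (int i = 0; i < N; ++i) {
      int c[3];
      for (int a = 0; a < 3; ++a) {
        double x = pos(i, a);
        if (periodic[a]) { x -= box[a] * std::floor(x / box[a]); }
        int k = (int)std::floor(x / box[a] * nc[a]);
        if (k < 0) k = 0;
        if (k >= nc[a]) k = nc[a] - 1;
        c[a] = k;
      }
      int idx = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      cellof[i] = idx;
      nxt[i] = head[idx];
      head[idx] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c0 = (cz * nc[1] + cy) * nc[0] + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ex = cx + dx, ey = cy + dy, ez = cz + dz;
                if (periodic[0]) ex = (ex + nc[0]) % nc[0];
                if (periodic[1]) ey = (ey + nc[1]) % nc[1];
                if (periodic[2]) ez = (ez + nc[2]) % nc[2];
                if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
                    ez < 0 || ez >= nc[2]) continue;
                int c1 = (ez * nc[1] + ey) * nc[0] + ex;
                if (c1 < c0) continue;  // each cell pair once
                for (int i = head[c0]; i != -1; i = nxt[i])
                  for (int j = (c1 == c0 ? nxt[i] : head[c1]); j != -1; j = nxt[j]) {
                    double ddx = mindelta(pos(j,0) - pos(i,0), box[0], periodic[0]);
                    double ddy = mindelta(pos(j,1) - pos(i,1), box[1], periodic[1]);
                    double ddz = mindelta(pos(j,2) - pos(i,2), box[2], periodic[2]);
                    double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
                    double cc = radii[i] + radii[j] + gap;
                    if (d2 <= cc * cc) {
                      if (i < j) { pi.push_back(i + 1); pj.push_back(j + 1); }
                      else       { pi.push_back(j + 1); pj.push_back(i + 1); }
                    }
                  }
              }
        }
  }

  IntegerMatrix out((int)pi.size(), 2);
  for (int k = 0; k < (int)pi.size(); ++k) { out(k,0) = pi[k]; out(k,1) = pj[k]; }
  return out;
}

// Is each query point covered by any sphere (minimum-image aware)?
// [[Rcpp::export]]
LogicalVector cpp_points_covered(NumericMatrix pts, NumericMatrix pos,
                                 NumericVector radii, NumericVector box,
                                 LogicalVector periodic) {
  const int M = pts.nrow(), N = pos.nrow();
  LogicalVector out(M);
  double rmax = 0.0;
  for (int i = 0; i < N; ++i) rmax = std::max(rmax, radii[i]);
  // cell list over spheres, cell >= rmax so 27-cell search suffices
  int nc[3];
  bool cells_ok = true;
  for (int a = 0; a < 3; ++a) {
    nc[a] = (int)std::floor(box[a] / rmax);
    if (nc[a] < 1) nc[a] = 1;
    if (periodic[a] && nc[a] < 3) cells_ok = false;
  }
  if (!cells_ok || N < 100) {
    for (int p = 0; p < M; ++p) {
      bool cov = false;
      for (int i = 0; i < N && !cov; ++i) {
        double dx = mindelta(pts(p,0) - pos(i,0), box[0], periodic[0]);
        double dy = mindelta(pts(p,1) - pos(i,1), box[1], periodic[1]);
        double dz = mindelta(pts(p,2) - pos(i,2), box[2], periodic[2]);
        cov = dx*dx + dy*dy + dz*dz <= radii[i] * radii[i];
      }
      out[p] = cov;
    }
    return out;
  }
  long ntot = (long)nc[0] * nc[1] * nc[2];
  std::vector<int> head(ntot, -1), nxt(N, -1);
  for (int i = 0; i < N; ++i) {
    int c[3];
    for (int a = 0; a < 3; ++a) {
      double x = pos(i, a);
      if (periodic[a]) x -= box[a] * std::floor(x / box[a]);
      int k = (int)std::floor(x / box[a] * nc[a]);
      c[a] = std::min(std::max(k, 0), nc[a] - 1);
    }
    int idx = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    nxt[i] = head[idx];
    head[idx] = i;
  }
  for (int p = 0; p < M; ++p) {
    int c[3];
    for (int a = 0; a < 3; ++a) {
      double x = pts(p, a);
      if (periodic[a]) x -= box[a] * std::floor(x / box[a]);
      int k = (int)std::floor(x / box[a] * nc[a]);
      c[a] = std::min(std::max(k, 0), nc[a] - 1);
    }
    bool cov = false;
    for (int dz = -1; dz <= 1 && !cov; ++dz)
      for (int dy = -1; dy <= 1 && !cov; ++dy)
        for (int dx = -1; dx <= 1 && !cov; ++dx) {
          int ex = c[0] + dx, ey = c[1] + dy, ez = c[2] + dz;
          if (periodic[0]) ex = (ex + nc[0]) % nc[0];
          if (periodic[1]) ey = (ey + nc[1]) % nc[1];
          if (periodic[2]) ez = (ez + nc[2]) % nc[2];
          if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
              ez < 0 || ez >= nc[2]) continue;
          int c1 = (ez * nc[1] + ey) * nc[0] + ex;
          for (int i = head[c1]; i != -1 && !cov; i = nxt[i]) {
            double ddx = mindelta(pts(p,0) - pos(i,0), box[0], periodic[0]);
            double ddy = mindelta(pts(p,1) - pos(i,1), box[1], periodic[1]);
            double ddz = mindelta(pts(p,2) - pos(i,2), box[2], periodic[2]);
            cov = ddx*ddx + ddy*ddy + ddz*ddz <= radii[i] * radii[i];
          }
        }
    out[p] = cov;
  }
  return out;
}
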