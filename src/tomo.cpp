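// Voxel-volume kernels: sphere voxelization, exact squared Euclidean distance
// transform (Felzenszwalb-Huttenlocher separable algorithm), separable
// Gaussian smoothing, and marker-controlled watershed by priority flooding.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Voxel centre convention: origin + (i + 0.5) * pitch, 0-based i.
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix pos, NumericVector radii,
                           NumericVector origin, IntegerVector dims,
                           double pitch, NumericVector box,
                           LogicalVector periodic) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector grid((R_xlen_t)nx * ny * nz);
  const int N = pos.nrow();
  for (int s = 0; s < N; ++s) {
    double cx = pos(s, 0) - origin[0];
    double cy = pos(s, 1) - origin[1];
    double cz = pos(s, 2) - origin[2];
    double r = radii[s], r2 = r * r;
    int i0 = (int)std::floor((cx - r) / pitch - 0.5) - 1;
    int i1 = (int)std::ceil((cx + r) / pitch - 0.5) + 1;
    int j0 = (int)std::floor((cy - r) / pitch - 0.5) - 1;
    int j1 = (int)std::ceil((cy + r) / pitch - 0.5) + 1;
    int k0 = (int)std::floor((cz - r) / pitch - 0.5) - 1;
    int k1 = (int)std::ceil((cz + r) / pitch - 0.5) + 1;
    for (int k = k0; k <= k1; ++k) {
      int kk = k;
      if (periodic[2]) { kk = ((k % nz) + nz) % nz; }
      else if (k < 0 || k >= nz) continue;
      double dz = (k + 0.5) * pitch - cz;
      for (int j = j0; j <= j1; ++j) {
        int jj = j;
        if (periodic[1]) { jj = ((j % ny) + ny) % ny; }
        else if (j < 0 || j >= ny) continue;
        double dy = (j + 0.5) * pitch - cy;
        for (int i = i0; i <= i1; ++i) {
          int ii = i;
          if (periodic[0]) { ii = ((i % nx) + nx) % nx; }
          else if (i < 0 || i >= nx) continue;
          double dx = (i + 0.5) * pitch - cx;
          if (dx * dx + dy * dy + dz * dz <= r2)
            grid[((R_xlen_t)kk * ny + jj) * nx + ii] = 1;
        }
      }
    }
  }
  return grid;
}

namespace {
// 1-D squared distance transform (lower envelope of parabolas)
void dt1d(const double *f, double *d, int n, std::vector<int> &v,
          std::vector<double> &z) {
  v.resize(n);
  z.resize(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}
}  // namespace

// Squared distance (voxel units) from each foreground voxel to the nearest
// background voxel; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector grid, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e18;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = (grid[i] != 0) ? INF : 0.0;
  std::vector<int> v;
  std::vector<double> z;
  std::vector<double> f(std::max(nx, std::max(ny, nz))),
      d(std::max(nx, std::max(ny, nz)));
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[((R_xlen_t)k * ny + j) * nx + i];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) D[((R_xlen_t)k * ny + j) * nx + i] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[((R_xlen_t)k * ny + j) * nx + i];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) D[((R_xlen_t)k * ny + j) * nx + i] = d[k];
    }
  return D;
}

// Separable Gaussian blur, sd in voxels, truncated at 3 sd. Edge: renormalized.
// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector vol, IntegerVector dims, double sd) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sd <= 0) return clone(vol);
  int half = std::max(1, (int)std::ceil(3.0 * sd));
  std::vector<double> ker(2 * half + 1);
  for (int t = -half; t <= half; ++t)
    ker[t + half] = std::exp(-0.5 * t * t / (sd * sd));
  NumericVector A = clone(vol), B((R_xlen_t)nx * ny * nz);
  auto pass = [&](NumericVector &src, NumericVector &dst, int axis) {
    int nn[3] = {nx, ny, nz};
    R_xlen_t str[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
    int na = nn[axis];
    R_xlen_t sa = str[axis];
    int b1 = (axis == 0) ? 1 : 0;
    int b2 = (axis == 2) ? 1 : 2;
    for (int q = 0; q < nn[b2]; ++q)
      for (int p = 0; p < nn[b1]; ++p) {
        R_xlen_t base = (R_xlen_t)p * str[b1] + (R_xlen_t)q * str[b2];
        for (int t = 0; t < na; ++t) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, t - half), hi = std::min(na - 1, t + half);
          for (int u = lo; u <= hi; ++u) {
            double w = ker[u - t + half];
            acc += w * src[base + (R_xlen_t)u * sa];
            wsum += w;
          }
          dst[base + (R_xlen_t)t * sa] = acc / wsum;
        }
      }
  };
  pass(A, B, 0);
  pass(B, A, 1);
  pass(A, B, 2);
  return B;
}

// Marker-controlled watershed: flood the (higher = earlier) priority map from
// labelled markers, restricted to mask > 0. 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  struct Node {
    double p;
    R_xlen_t idx;
    long order;
    bool operator<(const Node &o) const {
      if (p != o.p) return p < o.p;       // max-heap on priority
      return order > o.order;             // FIFO tie-break -> deterministic
    }
  };
  std::priority_queue<Node> pq;
  long counter = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    lab[i] = markers[i];
    if (markers[i] > 0) pq.push({priority[i], i, counter++});
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    R_xlen_t idx = nd.idx;
    int L = lab[idx];
    int i = (int)(idx % nx), j = (int)((idx / nx) % ny), k = (int)(idx / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t nidx = ((R_xlen_t)kk * ny + jj) * nx + ii;
      if (mask[nidx] <= 0 || lab[nidx] != 0) continue;
      lab[nidx] = L;
      pq.push({priority[nidx], nidx, counter++});
    }
  }
  return lab;
}

// Strict-ish local maxima of a smoothed field within a mask (26-neighbourhood,
// value >= all neighbours and > floor). Plateaus keep the lowest linear index.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector mask,
                               IntegerVector dims, double floor_value) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<R_xlen_t> out;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = ((R_xlen_t)k * ny + j) * nx + i;
        if (mask[idx] <= 0) continue;
        double v = vol[idx];
        if (v <= floor_value) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1 && ismax; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              R_xlen_t nidx = ((R_xlen_t)kk * ny + jj) * nx + ii;
              double w = vol[nidx];
              if (w > v) ismax = false;
              else if (w == v && nidx < idx) ismax = false;
            }
        if (ismax) out.push_back(idx + 1);  // 1-based
      }
  IntegerVector res((int)out.size());
  for (int t = 0; t < (int)out.size(); ++t) res[t] = (int)out[t];
  return res;
}

// Smooth 3-D Gaussian random field: white noise (splitmix64) blurred with sd,
// then standardized to zero mean / unit sd. Used for surface deformation.
// [[Rcpp::export]]
NumericVector cpp_noise_field(IntegerVector dims, double sd, double seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector W(n);
  std::uint64_t s = (std::uint64_t)seed;
  if (!s) s = 0x9e3779b97f4a7c15ULL;
  bool has_spare = false;
  double spare = 0;
  auto unif = [&]() {
    s += 0x9e3779b97f4a7c15ULL;
    std::uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  };
  for (R_xlen_t i = 0; i < n; ++i) {
    if (has_spare) { W[i] = spare; has_spare = false; continue; }
    double u1 = 0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    W[i] = m * std::cos(2 * M_PI * u2);
    spare = m * std::sin(2 * M_PI * u2);
    has_spare = true;
  }
  NumericVector B = cpp_blur3(W, dims, sd);
  double mu = 0, s2 = 0;
  for (R_xlen_t i = 0; i < n; ++i) mu += B[i];
  mu /= n;
  for (R_xlen_t i = 0; i < n; ++i) s2 += (B[i] - mu) * (B[i] - mu);
  s2 = std::sqrt(s2 / n);
  if (s2 <= 0) s2 = 1;
  for (R_xlen_t i = 0; i < n; ++i) B[i] = (B[i] - mu) / s2;
  return B;
}
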