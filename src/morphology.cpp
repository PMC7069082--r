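// Low-level voxel morphology: connected components, Euclidean distance
// transform, and topology-preserving 3D thinning. All operate on logical
// vectors in R's column-major layout with explicit dims.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && manh > 1) continue;
            // connectivity 18 would be manh <= 2; only 6/26 used here
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher),
// anisotropic step w (distance between adjacent samples).
static void dt1d(std::vector<double> &f, double w) {
  const int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
  f = d;
}

// Distance (in mm) from each voxel to the nearest background voxel.
// Foreground voxels on the volume boundary see the implicit outside as
// background only through real background voxels inside the array.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> line;
  // x passes
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = line[x];
    }
  // y passes
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = line[y];
    }
  // z passes
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = line[z];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---- 3D thinning -----------------------------------------------------------
// Iterative border peeling in six directional subiterations. A voxel is
// deleted only when it is a simple point (deletion preserves both the
// foreground 26-topology and the background 6-topology; Bertrand-Malandain
// characterization: T26 == 1 and T6 == 1) and not a curve endpoint.

// Gather the 3x3x3 neighborhood occupancy (out-of-volume = background).
static void neighborhood(const std::vector<char> &m, int x, int y, int z,
                         int nx, int ny, int nz, char nb[27]) {
  int t = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++t) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          nb[t] = 0;
        else
          nb[t] = m[idx3(xx, yy, zz, nx, ny)];
      }
}

static inline int off_idx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// Number of 26-connected components of foreground in N26* (center excluded).
static int t26(const char nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> st(1, s);
    seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c - 9 * cz) / 3, cx = c - 9 * cz - 3 * cy;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2)
              continue;
            int j = xx + 3 * yy + 9 * zz;
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  return comps;
}

// Number of 6-connected components of background restricted to the
// 18-neighborhood that touch a face neighbor of the center.
static int t6(const char nb[27]) {
  // N18 = offsets with |dx|+|dy|+|dz| in {1,2}
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[off_idx(dx, dy, dz)] = (m >= 1 && m <= 2);
      }
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    // only count components reachable from a face neighbor
    int sz = s / 9, sy = (s - 9 * sz) / 3, sx = s - 9 * sz - 3 * sy;
    int sm = std::abs(sx - 1) + std::abs(sy - 1) + std::abs(sz - 1);
    if (sm != 1) continue; // seed only at face neighbors
    ++comps;
    std::vector<int> st(1, s);
    seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c - 9 * cz) / 3, cx = c - 9 * cz - 3 * cy;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2) continue;
        int j = xx + 3 * yy + 9 * zz;
        if (!in18[j] || seen[j] || nb[j]) continue;
        seen[j] = true;
        st.push_back(j);
      }
    }
  }
  return comps;
}

static inline int n26_count(const char nb[27]) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++c;
  return c;
}

static inline bool is_simple(const char nb[27]) {
  return t26(nb) == 1 && t6(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> m(n);
  for (int i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<int> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = idx3(x, y, z, nx, ny);
            if (!m[i]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            bool border =
              (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
               zz >= nz) ? true : !m[idx3(xx, yy, zz, nx, ny)];
            if (!border) continue;
            neighborhood(m, x, y, z, nx, ny, nz, nb);
            int cnt = n26_count(nb);
            if (cnt <= 1) continue; // endpoint or isolated voxel: keep
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential deletion with re-check preserves topology exactly
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int z = i / (nx * ny);
        int rem = i - z * nx * ny;
        int y = rem / nx;
        int x = rem - y * nx;
        neighborhood(m, x, y, z, nx, ny, nz, nb);
        int cnt = n26_count(nb);
        if (cnt <= 1) continue;
        if (is_simple(nb)) { m[i] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// Exact exponential convolution of a piecewise-linear curve (recursive per
// segment); the kinetics hot loop.
// [[Rcpp::export]]
NumericVector cpp_exp_convolve(NumericVector times, NumericVector cp,
                               double beta) {
  const int n = times.size();
  NumericVector E(n);
  for (int i = 0; i + 1 < n; ++i) {
    double h = times[i + 1] - times[i];
    double a = cp[i];
    double b = (cp[i + 1] - cp[i]) / h;
    double em = std::exp(-beta * h);
    E[i + 1] = E[i] * em + a * (1.0 - em) / beta +
      b * (h / beta - (1.0 - em) / (beta * beta));
  }
  return E;
}
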