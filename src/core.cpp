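#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids are R arrays in column-major order: index = i + nx*(j + ny*k),
// 0-based (i fastest = in-plane x, k = slice axis).

static inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at fractional voxel coordinates (0-based, voxel
// centers at integer coords). Points outside the grid evaluate to 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -1 || y < -1 || z < -1 || x > nx || y > ny || z > nz) {
      out[p] = 0.0; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w == 0.0) continue;
          double v = 0.0;
          if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
            v = vol[vidx(i, j, k, nx, ny)];
          acc += w * v;
        }
    out[p] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (BFS). connectivity in {6, 18, 26}; a 2D
// plane is the nz == 1 case (26 -> 8-connectivity in-plane).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector vol, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int a = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (a == 0) continue;
        if (connectivity == 6 && a > 1) continue;
        if (connectivity == 18 && a > 2) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  int nextlab = 0;
  std::queue<long long> q;
  for (long long s = 0; s < n; ++s) {
    if (!vol[s] || lab[s]) continue;
    ++nextlab;
    lab[s] = nextlab;
    q.push(s);
    while (!q.empty()) {
      long long c = q.front(); q.pop();
      int k = (int)(c / ((long long)nx * ny));
      int rem = (int)(c % ((long long)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (size_t t = 0; t < offs_i.size(); ++t) {
        int ii = i + offs_i[t], jj = j + offs_j[t], kk = k + offs_k[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        long long u = vidx(ii, jj, kk, nx, ny);
        if (vol[u] && !lab[u]) { lab[u] = nextlab; q.push(u); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope scan per axis). Distance of each foreground
// voxel to the nearest background voxel; 0 on background. Voxels outside the
// grid count as background (add a virtual border).
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double step) {
  const double INF = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector vol, IntegerVector dim,
                         NumericVector spacing, bool border_is_background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(n);
  for (long long s = 0; s < n; ++s) d[s] = vol[s] ? INF : 0.0;

  // pad each scan line with a virtual background sample just outside the grid
  int pad = border_is_background ? 1 : 0;
  std::vector<double> f, g;
  // x pass
  f.resize(nx + 2 * pad); g.resize(nx + 2 * pad);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i + pad] = d[vidx(i, j, k, nx, ny)];
      if (pad) { f[0] = 0.0; f[nx + 1] = 0.0; }
      dt1d(f, g, nx + 2 * pad, spacing[0]);
      for (int i = 0; i < nx; ++i) d[vidx(i, j, k, nx, ny)] = g[i + pad];
    }
  // y pass
  f.resize(ny + 2 * pad); g.resize(ny + 2 * pad);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j + pad] = d[vidx(i, j, k, nx, ny)];
      if (pad) { f[0] = 0.0; f[ny + 1] = 0.0; }
      dt1d(f, g, ny + 2 * pad, spacing[1]);
      for (int j = 0; j < ny; ++j) d[vidx(i, j, k, nx, ny)] = g[j + pad];
    }
  // z pass
  f.resize(nz + 2 * pad); g.resize(nz + 2 * pad);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k + pad] = d[vidx(i, j, k, nx, ny)];
      if (pad) { f[0] = 0.0; f[nz + 1] = 0.0; }
      dt1d(f, g, nz + 2 * pad, spacing[2]);
      for (int k = 0; k < nz; ++k) d[vidx(i, j, k, nx, ny)] = g[k + pad];
    }
  d.attr("dim") = dim;
  return d;
}

// ---------------------------------------------------------------------------
// Topology-preserving curve thinning.
//
// A foreground voxel is "simple" (its deletion preserves digital topology in
// the (26, 6) adjacency pair) iff
//   (a) the foreground of its punctured 26-neighbourhood has exactly one
//       26-connected component, and
//   (b) the background of its 18-neighbourhood has exactly one 6-connected
//       component that is 6-adjacent to the voxel.
// Border voxels are deleted in increasing order of the interior distance
// transform (distance-ordered homotopic thinning), and voxels with at most
// one remaining foreground 26-neighbour are retained as curve endpoints.

struct Nbh {
  bool fg[27]; // 3x3x3, index di+1 + 3*(dj+1) + 9*(dk+1); centre = 13
};

static inline int nidx(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

static void load_nbh(const std::vector<char>& vol, int nx, int ny, int nz,
                     int i, int j, int k, Nbh& nb) {
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        bool v = false;
        if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
          v = vol[vidx(ii, jj, kk, nx, ny)] != 0;
        nb.fg[nidx(di, dj, dk)] = v;
      }
}

static int count_fg_neighbours(const Nbh& nb) {
  int c = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb.fg[t]) ++c;
  return c;
}

static bool is_simple(const Nbh& nb) {
  // (a) one 26-component of foreground in the punctured neighbourhood
  bool seen[27] = {false};
  int comp_fg = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb.fg[s] || seen[s]) continue;
    ++comp_fg;
    if (comp_fg > 1) return false;
    std::vector<int> stack = {s};
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || ii > 2 || jj < 0 || jj > 2 || kk < 0 || kk > 2) continue;
            int u = ii + 3 * jj + 9 * kk;
            if (u == 13 || u == c || seen[u] || !nb.fg[u]) continue;
            seen[u] = true; stack.push_back(u);
          }
    }
  }
  if (comp_fg != 1) return false;

  // (b) one 6-component of background within the 18-neighbourhood that
  //     contains a face neighbour of the centre
  auto in18 = [](int ii, int jj, int kk) {
    int a = std::abs(ii - 1) + std::abs(jj - 1) + std::abs(kk - 1);
    return a >= 1 && a <= 2;
  };
  bool seenb[27] = {false};
  int comp_bg = 0;
  static const int face[6] = {nidx(-1,0,0), nidx(1,0,0), nidx(0,-1,0),
                              nidx(0,1,0),  nidx(0,0,-1), nidx(0,0,1)};
  for (int fidx = 0; fidx < 6; ++fidx) {
    int s = face[fidx];
    if (nb.fg[s] || seenb[s]) continue;
    ++comp_bg;
    if (comp_bg > 1) return false;
    std::vector<int> stack = {s};
    seenb[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int ii = ci + d6[t][0], jj = cj + d6[t][1], kk = ck + d6[t][2];
        if (ii < 0 || ii > 2 || jj < 0 || jj > 2 || kk < 0 || kk > 2) continue;
        if (!in18(ii, jj, kk)) continue;
        int u = ii + 3 * jj + 9 * kk;
        if (seenb[u] || nb.fg[u]) continue;
        seenb[u] = true; stack.push_back(u);
      }
    }
  }
  return comp_bg == 1;
}

// Physically weighted 26-neighbourhood geodesic distance (Dijkstra) inside
// the foreground, from one or more start voxels (linear 0-based indices).
// Background voxels get -1.
// [[Rcpp::export]]
NumericVector cpp_geodesic_bfs(LogicalVector vol, IntegerVector dim,
                               NumericVector spacing, NumericVector starts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  NumericVector d(n, -1.0);
  typedef std::pair<double, long long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int t = 0; t < starts.size(); ++t) {
    long long s = (long long)starts[t];
    if (s >= 0 && s < n && vol[s]) { d[s] = 0.0; pq.push(QE(0.0, s)); }
  }
  double step[3][3][3];
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        step[di + 1][dj + 1][dk + 1] = std::sqrt(
          di * di * spacing[0] * spacing[0] +
          dj * dj * spacing[1] * spacing[1] +
          dk * dk * spacing[2] * spacing[2]);
  while (!pq.empty()) {
    double dc = pq.top().first;
    long long c = pq.top().second; pq.pop();
    if (dc > d[c]) continue;
    int k = (int)(c / ((long long)nx * ny));
    int rem = (int)(c % ((long long)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          long long u = vidx(ii, jj, kk, nx, ny);
          if (!vol[u]) continue;
          double nd = dc + step[di + 1][dj + 1][dk + 1];
          if (d[u] < 0 || nd < d[u]) { d[u] = nd; pq.push(QE(nd, u)); }
        }
  }
  d.attr("dim") = dim;
  return d;
}

// Foreground voxels that are 26-neighbourhood local maxima of a numeric
// field (background = -1 never wins).
// [[Rcpp::export]]
LogicalVector cpp_locmax26(NumericVector d, LogicalVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  LogicalVector out(n, false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long s = vidx(i, j, k, nx, ny);
        if (!vol[s]) continue;
        bool mx = true;
        for (int dk = -1; dk <= 1 && mx; ++dk)
          for (int dj = -1; dj <= 1 && mx; ++dj)
            for (int di = -1; di <= 1 && mx; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
              if (d[vidx(ii, jj, kk, nx, ny)] > d[s]) mx = false;
            }
        out[s] = mx;
      }
  out.attr("dim") = dim;
  return out;
}

// Anchored homotopic thinning: simple points (whose deletion preserves
// digital topology) are removed in increasing distance-transform order, so
// the survivors lie on the medial ridge. Anchor voxels — medialized
// geodesic extremities supplied by the caller — are never deleted;
// connectivity preservation then forces a one-voxel-wide medial path
// joining every anchor to survive. No endpoint heuristic is used, so no
// spurious tips can freeze mid-process.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector vol_in, IntegerVector dim,
                         NumericVector priority, LogicalVector anchor) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  std::vector<char> vol(n);
  for (long long s = 0; s < n; ++s) vol[s] = vol_in[s] ? 1 : 0;

  typedef std::pair<double, long long> QE; // (priority, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  auto is_border = [&](int i, int j, int k) {
    static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int t = 0; t < 6; ++t) {
      int ii = i + d6[t][0], jj = j + d6[t][1], kk = k + d6[t][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) return true;
      if (!vol[vidx(ii, jj, kk, nx, ny)]) return true;
    }
    return false;
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long s = vidx(i, j, k, nx, ny);
        if (vol[s] && !anchor[s] && is_border(i, j, k)) pq.push(QE(priority[s], s));
      }

  Nbh nb;
  while (!pq.empty()) {
    long long s = pq.top().second; pq.pop();
    if (!vol[s] || anchor[s]) continue;
    int k = (int)(s / ((long long)nx * ny));
    int rem = (int)(s % ((long long)nx * ny));
    int j = rem / nx, i = rem % nx;
    load_nbh(vol, nx, ny, nz, i, j, k, nb);
    if (count_fg_neighbours(nb) == 0) continue; // lone voxel: keep
    if (!is_simple(nb)) continue;
    vol[s] = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          long long u = vidx(ii, jj, kk, nx, ny);
          if (vol[u] && !anchor[u]) pq.push(QE(priority[u], u));
        }
  }

  LogicalVector out(n);
  for (long long s = 0; s < n; ++s) out[s] = vol[s] != 0;
  out.attr("dim") = dim;
  return out;
}
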