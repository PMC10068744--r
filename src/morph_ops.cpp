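// Morphological and geometric primitives on 3D voxel grids.
//
// Volumes have dim (Z, Y, X), column-major (z fastest), 0-based in C++.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline IntegerVector dims3(const SEXP a) {
  IntegerVector d = Rf_getAttrib(a, R_DimSymbol);
  if (d.size() != 3) stop("3D array expected");
  return d;
}

// ---------------------------------------------------------------------------
// 3D connected-component labeling (6 or 26 connectivity), BFS flood fill.
// Labels are assigned in raster-scan order of first contact (1, 2, ...).
// [[Rcpp::export]]
IntegerVector label_components_3d(IntegerVector mask, int connectivity) {
  IntegerVector d = dims3(mask);
  const int Z = d[0], Y = d[1], X = d[2];
  const size_t N = (size_t)Z * Y * X;
  IntegerVector lab(N);
  lab.attr("dim") = d;

  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < N; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int z = v % Z, y = (v / Z) % Y, x = v / ((size_t)Z * Y);
      for (auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X)
          continue;
        size_t u = zz + (size_t)Z * (yy + (size_t)Y * xx);
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Plane-wise 2D hole filling.  axis: 0 = fill in (y,x) slices for each z
// ("x-y planes"), 1 = (z,x) slices for each y, 2 = (z,y) slices for each x.
// Background is flood-filled (4-connectivity) from the slice border; any
// background voxel not reached is a hole and becomes foreground.
// [[Rcpp::export]]
IntegerVector fill_holes_slices(IntegerVector mask, int axis) {
  IntegerVector d = dims3(mask);
  const int Z = d[0], Y = d[1], X = d[2];
  IntegerVector out = clone(mask);
  out.attr("dim") = d;

  int A, B, S;  // slice dims A x B, S slices
  if (axis == 0) { A = Y; B = X; S = Z; }
  else if (axis == 1) { A = Z; B = X; S = Y; }
  else { A = Z; B = Y; S = X; }

  auto idx = [&](int s, int a, int b) -> size_t {
    int z, y, x;
    if (axis == 0) { z = s; y = a; x = b; }
    else if (axis == 1) { z = a; y = s; x = b; }
    else { z = a; y = b; x = s; }
    return z + (size_t)Z * (y + (size_t)Y * x);
  };

  std::vector<unsigned char> reach((size_t)A * B);
  std::vector<int> stack;
  for (int s = 0; s < S; ++s) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int a = 0; a < A; ++a)
      for (int b = 0; b < B; ++b) {
        if (a != 0 && a != A - 1 && b != 0 && b != B - 1) continue;
        if (out[idx(s, a, b)] == 0 && !reach[a + (size_t)A * b]) {
          reach[a + (size_t)A * b] = 1;
          stack.push_back(a + A * b);
        }
      }
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int a = v % A, b = v / A;
      const int da[4] = {1, -1, 0, 0}, db[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int aa = a + da[t], bb = b + db[t];
        if (aa < 0 || aa >= A || bb < 0 || bb >= B) continue;
        if (!reach[aa + (size_t)A * bb] && out[idx(s, aa, bb)] == 0) {
          reach[aa + (size_t)A * bb] = 1;
          stack.push_back(aa + A * bb);
        }
      }
    }
    for (int b = 0; b < B; ++b)
      for (int a = 0; a < A; ++a)
        if (out[idx(s, a, b)] == 0 && !reach[a + (size_t)A * b])
          out[idx(s, a, b)] = 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher squared
// distance, separable).  Input: seed mask (non-zero = distance 0).  spacing:
// per-axis voxel size (z, y, x).  Returns Euclidean distance (not squared).
static void dt1d(std::vector<double>& f, std::vector<double>& dout,
                 std::vector<int>& v, std::vector<double>& zb, int n,
                 double step) {
  const double INF = 1e50;
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * q - 2.0 * s2 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    dout[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_from_seeds(IntegerVector seeds, NumericVector spacing) {
  IntegerVector d = dims3(seeds);
  const int Z = d[0], Y = d[1], X = d[2];
  const size_t N = (size_t)Z * Y * X;
  const double INF = 1e50;
  NumericVector D(N);
  D.attr("dim") = d;
  for (size_t i = 0; i < N; ++i) D[i] = seeds[i] ? 0.0 : INF;

  int mx = std::max(Z, std::max(Y, X));
  std::vector<double> f(mx), dout(mx), zb(mx + 1);
  std::vector<int> v(mx);

  // along z
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      double* col = D.begin() + (size_t)Z * (y + (size_t)Y * x);
      for (int z = 0; z < Z; ++z) f[z] = col[z];
      dt1d(f, dout, v, zb, Z, spacing[0]);
      for (int z = 0; z < Z; ++z) col[z] = dout[z];
    }
  // along y
  for (int x = 0; x < X; ++x)
    for (int z = 0; z < Z; ++z) {
      for (int y = 0; y < Y; ++y)
        f[y] = D[z + (size_t)Z * (y + (size_t)Y * x)];
      dt1d(f, dout, v, zb, Y, spacing[1]);
      for (int y = 0; y < Y; ++y)
        D[z + (size_t)Z * (y + (size_t)Y * x)] = dout[y];
    }
  // along x
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      for (int x = 0; x < X; ++x)
        f[x] = D[z + (size_t)Z * (y + (size_t)Y * x)];
      dt1d(f, dout, v, zb, X, spacing[2]);
      for (int x = 0; x < X; ++x)
        D[z + (size_t)Z * (y + (size_t)Y * x)] = dout[x];
    }
  for (size_t i = 0; i < N; ++i) D[i] = std::sqrt(D[i]);
  return D;
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential thinning to a 1-voxel medial skeleton.
//
// A foreground voxel is "simple" when deleting it does not change topology,
// characterized by topological numbers T26 = 1 (one 26-component of
// foreground in the punctured 3x3x3 neighborhood) and T6 = 1 (one
// 6-component of background within the 18-neighborhood touching a face
// neighbor).  Six directional sub-iterations delete simple, non-endpoint
// border points until stabilization; deletions are sequential with
// re-checking, which guarantees topology preservation.

static const int NB26[26][3] = {
    {-1, -1, -1}, {0, -1, -1}, {1, -1, -1}, {-1, 0, -1}, {0, 0, -1},
    {1, 0, -1},   {-1, 1, -1}, {0, 1, -1},  {1, 1, -1},  {-1, -1, 0},
    {0, -1, 0},   {1, -1, 0},  {-1, 0, 0},  {1, 0, 0},   {-1, 1, 0},
    {0, 1, 0},    {1, 1, 0},   {-1, -1, 1}, {0, -1, 1},  {1, -1, 1},
    {-1, 0, 1},   {0, 0, 1},   {1, 0, 1},   {-1, 1, 1},  {0, 1, 1},
    {1, 1, 1}};

static bool nb_cube(const unsigned char* m, int Z, int Y, int X, int z, int y,
                    int x, bool nb[3][3][3]) {
  // fills 3x3x3 foreground map around (z,y,x); center included
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = false;
        if (zz >= 0 && zz < Z && yy >= 0 && yy < Y && xx >= 0 && xx < X)
          v = m[zz + (size_t)Z * (yy + (size_t)Y * xx)] != 0;
        nb[dz + 1][dy + 1][dx + 1] = v;
      }
  return true;
}

static int t26(const bool nb[3][3][3]) {
  // 26-components of foreground among the 26 neighbors (center excluded)
  bool seen[3][3][3] = {{{false}}};
  int ncomp = 0;
  int stack[26][3];
  for (int dx = 0; dx < 3; ++dx)
    for (int dy = 0; dy < 3; ++dy)
      for (int dz = 0; dz < 3; ++dz) {
        if (dz == 1 && dy == 1 && dx == 1) continue;
        if (!nb[dz][dy][dx] || seen[dz][dy][dx]) continue;
        ++ncomp;
        int top = 0;
        stack[top][0] = dz; stack[top][1] = dy; stack[top][2] = dx;
        seen[dz][dy][dx] = true;
        ++top;
        while (top > 0) {
          --top;
          int cz = stack[top][0], cy = stack[top][1], cx = stack[top][2];
          for (int ex = -1; ex <= 1; ++ex)
            for (int ey = -1; ey <= 1; ++ey)
              for (int ez = -1; ez <= 1; ++ez) {
                int nz = cz + ez, ny = cy + ey, nx2 = cx + ex;
                if (nz < 0 || nz > 2 || ny < 0 || ny > 2 || nx2 < 0 || nx2 > 2)
                  continue;
                if (nz == 1 && ny == 1 && nx2 == 1) continue;
                if (nb[nz][ny][nx2] && !seen[nz][ny][nx2]) {
                  seen[nz][ny][nx2] = true;
                  stack[top][0] = nz; stack[top][1] = ny; stack[top][2] = nx2;
                  ++top;
                }
              }
        }
      }
  return ncomp;
}

static int t6(const bool nb[3][3][3]) {
  // 6-components of background within the 18-neighborhood that contain a
  // face neighbor of the center
  bool bg[3][3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) {
        int manh = std::abs(a - 1) + std::abs(b - 1) + std::abs(c - 1);
        bg[a][b][c] = (manh >= 1 && manh <= 2) && !nb[a][b][c];
      }
  bool seen[3][3][3] = {{{false}}};
  int ncomp = 0;
  int stack[18][3];
  const int fz[6] = {0, 2, 1, 1, 1, 1}, fy[6] = {1, 1, 0, 2, 1, 1},
            fx[6] = {1, 1, 1, 1, 0, 2};
  for (int s = 0; s < 6; ++s) {
    int dz = fz[s], dy = fy[s], dx = fx[s];
    if (!bg[dz][dy][dx] || seen[dz][dy][dx]) continue;
    ++ncomp;
    int top = 0;
    stack[top][0] = dz; stack[top][1] = dy; stack[top][2] = dx;
    seen[dz][dy][dx] = true;
    ++top;
    while (top > 0) {
      --top;
      int cz = stack[top][0], cy = stack[top][1], cx = stack[top][2];
      const int da[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                            {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
      for (int t = 0; t < 6; ++t) {
        int nz = cz + da[t][0], ny = cy + da[t][1], nx2 = cx + da[t][2];
        if (nz < 0 || nz > 2 || ny < 0 || ny > 2 || nx2 < 0 || nx2 > 2)
          continue;
        if (bg[nz][ny][nx2] && !seen[nz][ny][nx2]) {
          seen[nz][ny][nx2] = true;
          stack[top][0] = nz; stack[top][1] = ny; stack[top][2] = nx2;
          ++top;
        }
      }
    }
  }
  return ncomp;
}

static inline bool is_simple(const bool nb[3][3][3]) {
  return t26(nb) == 1 && t6(nb) == 1;
}

static inline int n_neighbors26(const bool nb[3][3][3]) {
  int n = 0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c)
        if (!(a == 1 && b == 1 && c == 1) && nb[a][b][c]) ++n;
  return n;
}

// [[Rcpp::export]]
IntegerVector skeletonize3d(IntegerVector mask) {
  IntegerVector d = dims3(mask);
  const int Z = d[0], Y = d[1], X = d[2];
  const size_t N = (size_t)Z * Y * X;
  std::vector<unsigned char> m(N);
  for (size_t i = 0; i < N; ++i) m[i] = mask[i] != 0;

  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool nb[3][3][3];
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int x = 0; x < X; ++x)
        for (int y = 0; y < Y; ++y)
          for (int z = 0; z < Z; ++z) {
            size_t i = z + (size_t)Z * (y + (size_t)Y * x);
            if (!m[i]) continue;
            int zz = z + dirs[dir][0], yy = y + dirs[dir][1],
                xx = x + dirs[dir][2];
            bool border = (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 ||
                           xx >= X)
                              ? true
                              : m[zz + (size_t)Z * (yy + (size_t)Y * xx)] == 0;
            if (!border) continue;
            nb_cube(m.data(), Z, Y, X, z, y, x, nb);
            if (n_neighbors26(nb) <= 1) continue;  // endpoint
            if (is_simple(nb)) cand.push_back(i);
          }
      for (size_t i : cand) {
        int z = i % Z, y = (i / Z) % Y, x = i / ((size_t)Z * Y);
        nb_cube(m.data(), Z, Y, X, z, y, x, nb);
        if (n_neighbors26(nb) <= 1) continue;
        if (is_simple(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  IntegerVector out(N);
  out.attr("dim") = d;
  for (size_t i = 0; i < N; ++i) out[i] = m[i];
  return out;
}

// ---------------------------------------------------------------------------
// Capsule rasterization of one vessel path (polyline with per-node radii).
// Computes, inside an inflated bounding box, the minimum distance to the
// polyline (linearly interpolated radius at the closest point) and updates
// three flag volumes: solid (solid tube), wall (hollow-vessel wall shell),
// lumen (hollow-vessel interior).  Units: voxels (isotropic rendering grid).
// [[Rcpp::export]]
void rasterize_path(NumericMatrix pts, NumericVector radii, bool hollow,
                    double wall, IntegerVector solid, IntegerVector wallv,
                    IntegerVector lumen) {
  IntegerVector d = dims3(solid);
  const int Z = d[0], Y = d[1], X = d[2];
  const int n = pts.nrow();
  if (n == 0) return;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double pad = rmax + 1.5;

  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], pts(i, a));
      hi[a] = std::max(hi[a], pts(i, a));
    }
  int z0 = std::max(0, (int)std::floor(lo[0] - pad));
  int z1 = std::min(Z - 1, (int)std::ceil(hi[0] + pad));
  int y0 = std::max(0, (int)std::floor(lo[1] - pad));
  int y1 = std::min(Y - 1, (int)std::ceil(hi[1] + pad));
  int x0 = std::max(0, (int)std::floor(lo[2] - pad));
  int x1 = std::min(X - 1, (int)std::ceil(hi[2] + pad));
  if (z1 < z0 || y1 < y0 || x1 < x0) return;

  const int BZ = z1 - z0 + 1, BY = y1 - y0 + 1, BX = x1 - x0 + 1;
  std::vector<double> dmin((size_t)BZ * BY * BX, 1e30);
  std::vector<double> rloc((size_t)BZ * BY * BX, 0.0);

  for (int i = 0; i + 1 < n || (n == 1 && i == 0); ++i) {
    double p0[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double p1[3];
    double r0 = radii[i], r1;
    if (n == 1) { p1[0] = p0[0]; p1[1] = p0[1]; p1[2] = p0[2]; r1 = r0; }
    else { p1[0] = pts(i+1,0); p1[1] = pts(i+1,1); p1[2] = pts(i+1,2); r1 = radii[i+1]; }
    double seg[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double L2 = seg[0] * seg[0] + seg[1] * seg[1] + seg[2] * seg[2];
    double rs = std::max(r0, r1) + 1.5;
    int sz0 = std::max(z0, (int)std::floor(std::min(p0[0], p1[0]) - rs));
    int sz1 = std::min(z1, (int)std::ceil(std::max(p0[0], p1[0]) + rs));
    int sy0 = std::max(y0, (int)std::floor(std::min(p0[1], p1[1]) - rs));
    int sy1 = std::min(y1, (int)std::ceil(std::max(p0[1], p1[1]) + rs));
    int sx0 = std::max(x0, (int)std::floor(std::min(p0[2], p1[2]) - rs));
    int sx1 = std::min(x1, (int)std::ceil(std::max(p0[2], p1[2]) + rs));
    for (int x = sx0; x <= sx1; ++x)
      for (int y = sy0; y <= sy1; ++y)
        for (int z = sz0; z <= sz1; ++z) {
          double w[3] = {z - p0[0], y - p0[1], x - p0[2]};
          double t = 0.0;
          if (L2 > 0)
            t = std::max(0.0, std::min(1.0, (w[0] * seg[0] + w[1] * seg[1] +
                                             w[2] * seg[2]) / L2));
          double dz = w[0] - t * seg[0], dy = w[1] - t * seg[1],
                 dx = w[2] - t * seg[2];
          double dist = std::sqrt(dz * dz + dy * dy + dx * dx);
          size_t bi = (z - z0) + (size_t)BZ * ((y - y0) + (size_t)BY * (x - x0));
          if (dist < dmin[bi]) {
            dmin[bi] = dist;
            rloc[bi] = r0 + t * (r1 - r0);
          }
        }
    if (n == 1) break;
  }

  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z) {
        size_t bi = (z - z0) + (size_t)BZ * ((y - y0) + (size_t)BY * (x - x0));
        if (dmin[bi] > rloc[bi]) continue;
        size_t gi = z + (size_t)Z * (y + (size_t)Y * x);
        if (!hollow) {
          solid[gi] = 1;
        } else if (dmin[bi] <= rloc[bi] - wall) {
          lumen[gi] = 1;
        } else {
          wallv[gi] = 1;
        }
      }
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, zero-padded borders renormalized by kernel mass.
// [[Rcpp::export]]
NumericVector gaussian_blur3d(NumericVector img, NumericVector sigma) {
  IntegerVector d = dims3(img);
  const int Z = d[0], Y = d[1], X = d[2];
  NumericVector cur = clone(img);
  cur.attr("dim") = d;

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kk(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      kk[i + r] = std::exp(-0.5 * i * i / (s * s));
      ksum += kk[i + r];
    }
    for (auto& v : kk) v /= ksum;
    NumericVector nxt((size_t)Z * Y * X);
    nxt.attr("dim") = d;
    const int dimlen = (axis == 0) ? Z : (axis == 1) ? Y : X;
    for (int x = 0; x < X; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          int pos = (axis == 0) ? z : (axis == 1) ? y : x;
          double acc = 0, wsum = 0;
          for (int i = -r; i <= r; ++i) {
            int p = pos + i;
            if (p < 0 || p >= dimlen) continue;
            int zz = z, yy = y, xx = x;
            if (axis == 0) zz = p; else if (axis == 1) yy = p; else xx = p;
            double w = kk[i + r];
            acc += w * cur[zz + (size_t)Z * (yy + (size_t)Y * xx)];
            wsum += w;
          }
          nxt[z + (size_t)Z * (y + (size_t)Y * x)] = acc / wsum;
        }
    cur = nxt;
  }
  return cur;
}

// ---------------------------------------------------------------------------
// 26-neighborhood edges between marked voxels (for skeleton graphs).
// Returns a 2-column matrix of 1-based linear indices (u < v).
// [[Rcpp::export]]
IntegerMatrix adjacency26(IntegerVector mask) {
  IntegerVector d = dims3(mask);
  const int Z = d[0], Y = d[1], X = d[2];
  std::vector<int> us, vs;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        size_t i = z + (size_t)Z * (y + (size_t)Y * x);
        if (!mask[i]) continue;
        for (auto& o : NB26) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X)
            continue;
          size_t j = zz + (size_t)Z * (yy + (size_t)Y * xx);
          if (j <= i || !mask[j]) continue;
          us.push_back((int)i + 1);
          vs.push_back((int)j + 1);
        }
      }
  IntegerMatrix out(us.size(), 2);
  for (size_t t = 0; t < us.size(); ++t) {
    out(t, 0) = us[t];
    out(t, 1) = vs[t];
  }
  return out;
}
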