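#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Voxel grids are stored column-major as in R: linear = i + nx*(j + ny*k), 0-based.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---- 26-neighbour offsets ------------------------------------------------

static void neighbour_offsets(int off[26][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off[n][0] = dx; off[n][1] = dy; off[n][2] = dz; ++n;
      }
}

// ---- region growing ------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, double lower, double upper) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<char> visited(n, 0);
  int off[26][3]; neighbour_offsets(off);
  std::queue<int> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2); // 0-based
    int id = lin(i, j, k, nx, ny);
    if (!visited[id]) { visited[id] = 1; out[id] = TRUE; q.push(id); }
  }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
    for (int m = 0; m < 26; ++m) {
      int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int id2 = lin(ii, jj, kk, nx, ny);
      if (visited[id2]) continue;
      visited[id2] = 1;
      double v = vol[id2];
      if (v >= lower && v <= upper) { out[id2] = TRUE; q.push(id2); }
    }
  }
  return out;
}

// ---- connected component labelling (26-connectivity) ---------------------

// Labels assigned in scan (linear-index) order, so label 1 contains the
// lexicographically smallest foreground voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int off[26][3]; neighbour_offsets(off);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next; q.push((int)start);
    while (!q.empty()) {
      int id = q.front(); q.pop();
      int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
      for (int m = 0; m < 26; ++m) {
        int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int id2 = lin(ii, jj, kk, nx, ny);
        if (mask[id2] && !lab[id2]) { lab[id2] = next; q.push(id2); }
      }
    }
  }
  return lab;
}

// ---- Euclidean distance transform (Felzenszwalb & Huttenlocher) ----------

static const double DT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double step) {
  int k = 0;
  v[0] = 0; z[0] = -DT_INF; z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step, s = 0.0;
    for (;;) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) --k; else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// Distance (mm) from every voxel centre to the nearest background voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t t = 0; t < n; ++t) g[t] = mask[t] ? DT_INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[lin(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[lin(i, j, k, nx, ny)] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[lin(i, j, k, nx, ny)];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[lin(i, j, k, nx, ny)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[lin(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[lin(i, j, k, nx, ny)] = d[k];
    }
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = std::sqrt(g[t]);
  return out;
}

// ---- tube rasterisation --------------------------------------------------

// Mark voxels whose centre lies within the (linearly interpolated) tube
// radius of the centerline polyline. Voxel-centre membership test, no
// anti-aliasing.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tube(NumericMatrix pts, NumericVector radii,
                                 IntegerVector dim, NumericVector spacing,
                                 NumericVector origin,
                                 Nullable<LogicalVector> base_ = R_NilValue) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out = base_.isNotNull() ? clone(LogicalVector(base_)) : LogicalVector(n);
  const int nseg = pts.nrow() - 1;
  for (int s = 0; s < nseg; ++s) {
    double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
    double bx = pts(s + 1, 0), by = pts(s + 1, 1), bz = pts(s + 1, 2);
    double ra = radii[s], rb = radii[s + 1];
    double rmax = std::max(ra, rb);
    double lox = std::min(ax, bx) - rmax, hix = std::max(ax, bx) + rmax;
    double loy = std::min(ay, by) - rmax, hiy = std::max(ay, by) + rmax;
    double loz = std::min(az, bz) - rmax, hiz = std::max(az, bz) + rmax;
    int i0 = std::max(0, (int)std::floor((lox - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((loy - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::floor((loz - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::ceil((hiz - origin[2]) / spacing[2]));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double len2 = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + k * spacing[2];
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + j * spacing[1];
        for (int i = i0; i <= i1; ++i) {
          double px = origin[0] + i * spacing[0];
          // clamped-t distance: joint caps fill the outer-bend wedges
          // between consecutive segment bands (ends are clipped by the
          // caller against the end planes to keep the tube flat-ended)
          double t = 0.5;
          if (len2 > 0)
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dx = px - (ax + t * ux), dy = py - (ay + t * uy), dz = pz - (az + t * uz);
          double r = ra + t * (rb - ra);
          if (dx * dx + dy * dy + dz * dz <= r * r)
            out[lin(i, j, k, nx, ny)] = TRUE;
        }
      }
    }
  }
  return out;
}

// ---- exact local background distance (sub-voxel misr) --------------------

// Minimal distance from each query point (world mm) to any background voxel
// centre, searched in a local box grown until a background voxel is found.
// Exact where trilinear interpolation of the EDT is biased (the EDT is a
// cone near the medial axis and interpolation clips its apex).
// [[Rcpp::export]]
NumericVector cpp_min_bg_dist(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix pts, NumericVector guess) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); ++p) {
    double best = R_PosInf;
    double R = guess[p];
    for (int attempt = 0; attempt < 10; ++attempt) {
      int i0 = std::max(0, (int)std::floor((pts(p, 0) - R - origin[0]) / spacing[0]));
      int i1 = std::min(nx - 1, (int)std::ceil((pts(p, 0) + R - origin[0]) / spacing[0]));
      int j0 = std::max(0, (int)std::floor((pts(p, 1) - R - origin[1]) / spacing[1]));
      int j1 = std::min(ny - 1, (int)std::ceil((pts(p, 1) + R - origin[1]) / spacing[1]));
      int k0 = std::max(0, (int)std::floor((pts(p, 2) - R - origin[2]) / spacing[2]));
      int k1 = std::min(nz - 1, (int)std::ceil((pts(p, 2) + R - origin[2]) / spacing[2]));
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            if (mask[lin(i, j, k, nx, ny)]) continue;
            double dx = origin[0] + i * spacing[0] - pts(p, 0);
            double dy = origin[1] + j * spacing[1] - pts(p, 1);
            double dz = origin[2] + k * spacing[2] - pts(p, 2);
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (d < best) best = d;
          }
      if (R_FINITE(best)) break;
      R *= 2.0;
    }
    out[p] = best;
  }
  return out;
}

// ---- separable Gaussian smoothing ----------------------------------------

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth3d(NumericVector vol, IntegerVector dim,
                                    double sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int half = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> kern(2 * half + 1);
  double s = 0;
  for (int t = -half; t <= half; ++t) {
    kern[t + half] = std::exp(-0.5 * t * t / (sigma_vox * sigma_vox));
    s += kern[t + half];
  }
  for (size_t t = 0; t < kern.size(); ++t) kern[t] /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int strides[3] = {1, nx, nx * ny};
  const int lens[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const int stride = strides[axis], len = lens[axis];
    // iterate over all 1D lines along this axis
    const int ou = axis == 0 ? nx : 1;
    const R_xlen_t nlines = n / len;
    for (R_xlen_t l = 0; l < nlines; ++l) {
      R_xlen_t base;
      if (axis == 0) base = l * nx;
      else if (axis == 1) base = (l % nx) + (l / nx) * (R_xlen_t)nx * ny;
      else base = l;
      (void)ou;
      for (int q = 0; q < len; ++q) {
        double acc = 0;
        for (int t = -half; t <= half; ++t) {
          int qq = q + t;
          if (qq < 0) qq = 0; else if (qq >= len) qq = len - 1;
          acc += kern[t + half] * a[base + (R_xlen_t)qq * stride];
        }
        b[base + (R_xlen_t)q * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---- marching tetrahedra -------------------------------------------------

// Kuhn/Freudenthal 6-tet cube decomposition (translation-consistent) of the
// voxel lattice; iso-surface at level `iso` with linear interpolation along
// crossed lattice edges (on a raw 0/1 mask this lands on edge midpoints).
// Triangles oriented with outward normals (inside = value > iso).

struct MTState {
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

// trilinear interpolation of the 8 cube-corner values at local coords
static inline double tril8(const double* fvc, double x, double y, double z) {
  return fvc[0] * (1 - x) * (1 - y) * (1 - z) + fvc[1] * x * (1 - y) * (1 - z) +
         fvc[2] * (1 - x) * y * (1 - z) + fvc[3] * x * y * (1 - z) +
         fvc[4] * (1 - x) * (1 - y) * z + fvc[5] * x * (1 - y) * z +
         fvc[6] * (1 - x) * y * z + fvc[7] * x * y * z;
}

// Crossing vertex on the (possibly diagonal) tet edge a-b. Along cell
// diagonals the trilinear field is cubic in t, so the linear estimate is
// refined by bisection onto the true trilinear iso-surface: this removes a
// direction-dependent caliber bias of several percent.
static int edge_vertex(MTState& st, int a, int b,
                       const int* la, const int* lb, // local 0/1 coords
                       const double* fvc, double iso,
                       const double* nxyz_a, const double* nxyz_b) {
  uint64_t lo = (uint64_t)std::min(a, b), hi = (uint64_t)std::max(a, b);
  uint64_t key = (lo << 32) | hi;
  auto it = st.vmap.find(key);
  if (it != st.vmap.end()) return it->second;
  int id = (int)st.vx.size();
  st.vmap.emplace(key, id);
  double va = tril8(fvc, la[0], la[1], la[2]);
  double vb = tril8(fvc, lb[0], lb[1], lb[2]);
  double t0 = 0.0, t1 = 1.0;
  bool a_below = va < iso;
  for (int it2 = 0; it2 < 30; ++it2) {
    double tm = 0.5 * (t0 + t1);
    double fm = tril8(fvc,
                      la[0] + tm * (lb[0] - la[0]),
                      la[1] + tm * (lb[1] - la[1]),
                      la[2] + tm * (lb[2] - la[2]));
    if ((fm < iso) == a_below) t0 = tm; else t1 = tm;
  }
  double t = 0.5 * (t0 + t1);
  if (t < 0.001) t = 0.001; else if (t > 0.999) t = 0.999;
  st.vx.push_back(nxyz_a[0] + t * (nxyz_b[0] - nxyz_a[0]));
  st.vy.push_back(nxyz_a[1] + t * (nxyz_b[1] - nxyz_a[1]));
  st.vz.push_back(nxyz_a[2] + t * (nxyz_b[2] - nxyz_a[2]));
  return id;
}

static void emit_tri(MTState& st, int v0, int v1, int v2,
                     const double* inward, const double* outward) {
  // orient so the normal points from inside to outside
  double e1x = st.vx[v1] - st.vx[v0], e1y = st.vy[v1] - st.vy[v0], e1z = st.vz[v1] - st.vz[v0];
  double e2x = st.vx[v2] - st.vx[v0], e2y = st.vy[v2] - st.vy[v0], e2z = st.vz[v2] - st.vz[v0];
  double nx = e1y * e2z - e1z * e2y;
  double ny = e1z * e2x - e1x * e2z;
  double nz = e1x * e2y - e1y * e2x;
  double ox = outward[0] - inward[0], oy = outward[1] - inward[1], oz = outward[2] - inward[2];
  if (nx * ox + ny * oy + nz * oz < 0) std::swap(v1, v2);
  st.tri.push_back(v0); st.tri.push_back(v1); st.tri.push_back(v2);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MTState st;
  // the 6 permutations of axis insertion order
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int tet_off[6][4][3];
  for (int p = 0; p < 6; ++p) {
    int cur[3] = {0, 0, 0};
    tet_off[p][0][0] = 0; tet_off[p][0][1] = 0; tet_off[p][0][2] = 0;
    for (int s = 0; s < 3; ++s) {
      cur[perms[p][s]] = 1;
      for (int d = 0; d < 3; ++d) tet_off[p][s + 1][d] = cur[d];
    }
  }
  double nodexyz[4][3];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // quick skip: all 8 cube corners on the same side of iso
        int sum = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              sum += field[lin(i + dx, j + dy, k + dz, nx, ny)] > iso ? 1 : 0;
        if (sum == 0 || sum == 8) continue;
        double fvc[8];
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              fvc[dx + 2 * dy + 4 * dz] = field[lin(i + dx, j + dy, k + dz, nx, ny)];
        for (int p = 0; p < 6; ++p) {
          int ids[4]; int vals[4]; double fv[4];
          for (int c = 0; c < 4; ++c) {
            int ii = i + tet_off[p][c][0], jj = j + tet_off[p][c][1], kk = k + tet_off[p][c][2];
            ids[c] = lin(ii, jj, kk, nx, ny);
            fv[c] = field[ids[c]];
            vals[c] = fv[c] > iso ? 1 : 0;
            nodexyz[c][0] = origin[0] + ii * spacing[0];
            nodexyz[c][1] = origin[1] + jj * spacing[1];
            nodexyz[c][2] = origin[2] + kk * spacing[2];
          }
          int nin = vals[0] + vals[1] + vals[2] + vals[3];
          if (nin == 0 || nin == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int c = 0; c < 4; ++c)
            for (int d = 0; d < 3; ++d)
              (vals[c] ? cin : cout)[d] += nodexyz[c][d];
          for (int d = 0; d < 3; ++d) { cin[d] /= nin; cout[d] /= (4 - nin); }
          if (nin == 1 || nin == 3) {
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if ((nin == 1 && vals[c]) || (nin == 3 && !vals[c])) lone = c;
            int vv[3], m = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == lone) continue;
              vv[m++] = edge_vertex(st, ids[lone], ids[c], tet_off[p][lone],
                                    tet_off[p][c], fvc, iso,
                                    nodexyz[lone], nodexyz[c]);
            }
            emit_tri(st, vv[0], vv[1], vv[2], cin, cout);
          } else { // nin == 2
            int a = -1, b = -1, c2 = -1, d2 = -1;
            for (int c = 0; c < 4; ++c) {
              if (vals[c]) { if (a < 0) a = c; else b = c; }
              else { if (c2 < 0) c2 = c; else d2 = c; }
            }
            int q0 = edge_vertex(st, ids[a], ids[c2], tet_off[p][a], tet_off[p][c2], fvc, iso, nodexyz[a], nodexyz[c2]);
            int q1 = edge_vertex(st, ids[a], ids[d2], tet_off[p][a], tet_off[p][d2], fvc, iso, nodexyz[a], nodexyz[d2]);
            int q2 = edge_vertex(st, ids[b], ids[d2], tet_off[p][b], tet_off[p][d2], fvc, iso, nodexyz[b], nodexyz[d2]);
            int q3 = edge_vertex(st, ids[b], ids[c2], tet_off[p][b], tet_off[p][c2], fvc, iso, nodexyz[b], nodexyz[c2]);
            emit_tri(st, q0, q1, q2, cin, cout);
            emit_tri(st, q0, q2, q3, cin, cout);
          }
        }
      }
  int nv = (int)st.vx.size(), nt = (int)st.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int t = 0; t < nv; ++t) { V(t, 0) = st.vx[t]; V(t, 1) = st.vy[t]; V(t, 2) = st.vz[t]; }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = st.tri[3 * t] + 1; T(t, 1) = st.tri[3 * t + 1] + 1; T(t, 2) = st.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---- Taubin (shrink-free) smoothing --------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix verts, IntegerMatrix tris,
                                int iterations, double lambda, double mu) {
  const int nv = verts.nrow(), nt = tris.nrow();
  std::vector<std::vector<int> > adj(nv);
  for (int t = 0; t < nt; ++t) {
    int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<double> x(nv), y(nv), z(nv), x2(nv), y2(nv), z2(nv);
  for (int v = 0; v < nv; ++v) { x[v] = verts(v, 0); y[v] = verts(v, 1); z[v] = verts(v, 2); }
  double factors[2] = {lambda, mu};
  for (int it = 0; it < iterations; ++it)
    for (int ph = 0; ph < 2; ++ph) {
      double f = factors[ph];
      for (int v = 0; v < nv; ++v) {
        if (adj[v].empty()) { x2[v] = x[v]; y2[v] = y[v]; z2[v] = z[v]; continue; }
        double mx = 0, my = 0, mz = 0;
        for (size_t m = 0; m < adj[v].size(); ++m) {
          mx += x[adj[v][m]]; my += y[adj[v][m]]; mz += z[adj[v][m]];
        }
        double inv = 1.0 / adj[v].size();
        x2[v] = x[v] + f * (mx * inv - x[v]);
        y2[v] = y[v] + f * (my * inv - y[v]);
        z2[v] = z[v] + f * (mz * inv - z[v]);
      }
      std::swap(x, x2); std::swap(y, y2); std::swap(z, z2);
    }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v) { out(v, 0) = x[v]; out(v, 1) = y[v]; out(v, 2) = z[v]; }
  return out;
}

// ---- 26-neighbour foreground voxel graph ---------------------------------

// Edges between foreground voxels for centerline path search. Returns
// 1-based indices into the foreground voxel list plus physical edge lengths.
// [[Rcpp::export]]
List cpp_voxel_graph(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> fgid(n, -1);
  std::vector<int> fglin;
  for (R_xlen_t t = 0; t < n; ++t)
    if (mask[t]) { fgid[t] = (int)fglin.size(); fglin.push_back((int)t); }
  // 13 forward offsets (half of the 26-neighbourhood)
  std::vector<int> from, to; std::vector<double> len;
  int off[26][3]; neighbour_offsets(off);
  for (size_t s = 0; s < fglin.size(); ++s) {
    int id = fglin[s];
    int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
    for (int m = 0; m < 26; ++m) {
      int dx = off[m][0], dy = off[m][1], dz = off[m][2];
      if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) continue; // forward only
      int ii = i + dx, jj = j + dy, kk = k + dz;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int id2 = lin(ii, jj, kk, nx, ny);
      if (fgid[id2] < 0) continue;
      from.push_back((int)s + 1);
      to.push_back(fgid[id2] + 1);
      double ex = dx * spacing[0], ey = dy * spacing[1], ez = dz * spacing[2];
      len.push_back(std::sqrt(ex * ex + ey * ey + ez * ez));
    }
  }
  IntegerVector fl(fglin.size());
  for (size_t s = 0; s < fglin.size(); ++s) fl[s] = fglin[s] + 1;
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["length"] = wrap(len), _["fg_linear"] = fl);
}
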