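#include <Rcpp.h>
#include <array>
#include <map>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Isosurface extraction on a voxel lattice, marching-cubes family.
// Each cube between two adjacent slices is decomposed into the six
// Freudenthal tetrahedra (all sharing the main diagonal); the decomposition
// is translation-compatible across the lattice, so crossing points on shared
// edges are computed bit-identically from both sides and the welded surface
// is watertight and topologically consistent without an ambiguous-case table.
// Coordinates are continuous voxel indices (i, j, k); the caller maps to mm.

namespace {

struct P3 { double x, y, z; };

// corner order inside a cube: bit0 = +i, bit1 = +j, bit2 = +k
const int TETS[6][4] = {
  {0, 1, 3, 7},
  {0, 1, 5, 7},
  {0, 2, 3, 7},
  {0, 2, 6, 7},
  {0, 4, 5, 7},
  {0, 4, 6, 7}
};

inline P3 corner_pos(int i, int j, int k0, int c) {
  P3 p;
  p.x = i + ((c & 1) ? 1.0 : 0.0);
  p.y = j + ((c & 2) ? 1.0 : 0.0);
  p.z = k0 + ((c & 4) ? 1.0 : 0.0);
  return p;
}

// order endpoints globally so both incident tetrahedra interpolate identically
inline bool lex_less(const P3 &a, const P3 &b) {
  if (a.z != b.z) return a.z < b.z;
  if (a.y != b.y) return a.y < b.y;
  return a.x < b.x;
}

inline P3 interp(const P3 &pa, double fa, const P3 &pb, double fb, double iso) {
  const P3 *p1 = &pa, *p2 = &pb;
  double f1 = fa, f2 = fb;
  if (!lex_less(pa, pb)) { p1 = &pb; p2 = &pa; f1 = fb; f2 = fa; }
  double t = (iso - f1) / (f2 - f1);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  P3 r;
  r.x = p1->x + t * (p2->x - p1->x);
  r.y = p1->y + t * (p2->y - p1->y);
  r.z = p1->z + t * (p2->z - p1->z);
  return r;
}

inline void push_tri(std::vector<double> &out, const P3 &a, const P3 &b,
                     const P3 &c, const P3 &inward) {
  // orient so the normal points from the high-value (inside) region outward
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
  double cx = (a.x + b.x + c.x) / 3.0, cy = (a.y + b.y + c.y) / 3.0,
         cz = (a.z + b.z + c.z) / 3.0;
  double dx = cx - inward.x, dy = cy - inward.y, dz = cz - inward.z;
  bool flip = (nx * dx + ny * dy + nz * dz) < 0.0;
  const P3 *v1 = &b, *v2 = &c;
  if (flip) { v1 = &c; v2 = &b; }
  out.push_back(a.x);  out.push_back(a.y);  out.push_back(a.z);
  out.push_back(v1->x); out.push_back(v1->y); out.push_back(v1->z);
  out.push_back(v2->x); out.push_back(v2->y); out.push_back(v2->z);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_march_layer(NumericMatrix f0, NumericMatrix f1, double iso,
                              int k0, Nullable<LogicalMatrix> keep_) {
  int nx = f0.nrow(), ny = f0.ncol();
  if (f1.nrow() != nx || f1.ncol() != ny)
    stop("slice shapes differ");
  bool have_keep = keep_.isNotNull();
  LogicalMatrix keep;
  if (have_keep) keep = LogicalMatrix(keep_);
  std::vector<double> out;
  out.reserve(1024);
  double fv[8];
  for (int j = 0; j < ny - 1; ++j) {
    for (int i = 0; i < nx - 1; ++i) {
      if (have_keep && !keep(i, j)) continue;
      fv[0] = f0(i, j);     fv[1] = f0(i + 1, j);
      fv[2] = f0(i, j + 1); fv[3] = f0(i + 1, j + 1);
      fv[4] = f1(i, j);     fv[5] = f1(i + 1, j);
      fv[6] = f1(i, j + 1); fv[7] = f1(i + 1, j + 1);
      bool any_in = false, any_out = false;
      for (int c = 0; c < 8; ++c) {
        if (fv[c] > iso) any_in = true; else any_out = true;
      }
      if (!any_in || !any_out) continue;
      for (int t = 0; t < 6; ++t) {
        int id[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
        int nin = 0;
        bool s[4];
        for (int v = 0; v < 4; ++v) { s[v] = fv[id[v]] > iso; if (s[v]) ++nin; }
        if (nin == 0 || nin == 4) continue;
        P3 pos[4];
        for (int v = 0; v < 4; ++v) pos[v] = corner_pos(i, j, k0, id[v]);
        // centroid of inside corners: used only for orientation
        P3 cin = {0, 0, 0};
        for (int v = 0; v < 4; ++v)
          if (s[v]) { cin.x += pos[v].x; cin.y += pos[v].y; cin.z += pos[v].z; }
        cin.x /= nin; cin.y /= nin; cin.z /= nin;
        if (nin == 1 || nin == 3) {
          bool want = (nin == 1);
          int apex = 0;
          for (int v = 0; v < 4; ++v) if (s[v] == want) apex = v;
          P3 e[3];
          int m = 0;
          for (int v = 0; v < 4; ++v) {
            if (v == apex) continue;
            e[m++] = interp(pos[apex], fv[id[apex]], pos[v], fv[id[v]], iso);
          }
          push_tri(out, e[0], e[1], e[2], cin);
        } else { // nin == 2 -> quad
          int a[2], b[2], na = 0, nb = 0;
          for (int v = 0; v < 4; ++v) { if (s[v]) a[na++] = v; else b[nb++] = v; }
          P3 q00 = interp(pos[a[0]], fv[id[a[0]]], pos[b[0]], fv[id[b[0]]], iso);
          P3 q01 = interp(pos[a[0]], fv[id[a[0]]], pos[b[1]], fv[id[b[1]]], iso);
          P3 q10 = interp(pos[a[1]], fv[id[a[1]]], pos[b[0]], fv[id[b[0]]], iso);
          P3 q11 = interp(pos[a[1]], fv[id[a[1]]], pos[b[1]], fv[id[b[1]]], iso);
          push_tri(out, q00, q01, q11, cin);
          push_tri(out, q00, q11, q10, cin);
        }
      }
    }
  }
  int ntri = (int)(out.size() / 9);
  NumericMatrix res(ntri, 9);
  for (int r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c) res(r, c) = out[(size_t)r * 9 + c];
  return res;
}

namespace {
struct QKeyHash {
  size_t operator()(const std::array<long long, 3> &k) const {
    uint64_t h = 1469598103934665603ull;
    for (long long v : k) {
      h ^= (uint64_t)v;
      h *= 1099511628211ull;
    }
    return (size_t)h;
  }
};
}

// Weld triangle soup (n x 9, xyz per vertex) into an indexed mesh.
// Vertices closer than tol are identified (quantized grid hashing).
// [[Rcpp::export]]
List cpp_weld_triangles(NumericMatrix tris, double tol) {
  int n = tris.nrow();
  std::unordered_map<std::array<long long, 3>, int, QKeyHash> seen;
  seen.reserve((size_t)n * 2);
  std::vector<double> verts;
  std::vector<int> faces;
  faces.reserve((size_t)n * 3);
  for (int r = 0; r < n; ++r) {
    int idx[3];
    for (int v = 0; v < 3; ++v) {
      double x = tris(r, v * 3), y = tris(r, v * 3 + 1), z = tris(r, v * 3 + 2);
      std::array<long long, 3> key = {
        (long long)std::llround(x / tol),
        (long long)std::llround(y / tol),
        (long long)std::llround(z / tol)
      };
      auto it = seen.find(key);
      if (it == seen.end()) {
        int id = (int)(verts.size() / 3);
        seen.emplace(key, id);
        verts.push_back(x); verts.push_back(y); verts.push_back(z);
        idx[v] = id;
      } else idx[v] = it->second;
    }
    if (idx[0] == idx[1] || idx[1] == idx[2] || idx[0] == idx[2]) continue;
    faces.push_back(idx[0]); faces.push_back(idx[1]); faces.push_back(idx[2]);
  }
  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[(size_t)i * 3];
    V(i, 1) = verts[(size_t)i * 3 + 1];
    V(i, 2) = verts[(size_t)i * 3 + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[(size_t)i * 3] + 1;     // 1-based for R
    F(i, 1) = faces[(size_t)i * 3 + 1] + 1;
    F(i, 2) = faces[(size_t)i * 3 + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Signed volume (divergence theorem) and surface area.
// [[Rcpp::export]]
NumericVector cpp_mesh_vol_area(NumericMatrix V, IntegerMatrix F) {
  double vol = 0.0, area = 0.0;
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);
    vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
            az * (bx * cy - by * cx)) / 6.0;
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double vx = cx - ax, vy = cy - ay, vz = cz - az;
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
           nz = ux * vy - uy * vx;
    area += 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
  }
  return NumericVector::create(vol, area);
}

// Watertightness (every directed edge matched by its reverse exactly once)
// and connected component count over the face graph.
// [[Rcpp::export]]
List cpp_mesh_topology(IntegerMatrix F, int nvert) {
  int nf = F.nrow();
  std::map<std::pair<int, int>, int> dir;
  for (int f = 0; f < nf; ++f) {
    int v[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      dir[std::make_pair(a, b)] += 1;
    }
  }
  bool watertight = true;
  int boundary = 0;
  for (auto &kv : dir) {
    if (kv.second != 1) { watertight = false; }
    auto rev = dir.find(std::make_pair(kv.first.second, kv.first.first));
    if (rev == dir.end()) { watertight = false; ++boundary; }
  }
  // union-find on vertices used by faces
  std::vector<int> parent(nvert);
  for (int i = 0; i < nvert; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < nf; ++f) {
    int a = find(F(f, 0) - 1), b = find(F(f, 1) - 1), c = find(F(f, 2) - 1);
    parent[a] = b; parent[find(b)] = find(c);
  }
  std::map<int, int> roots;
  std::vector<bool> used(nvert, false);
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) used[F(f, e) - 1] = true;
  for (int i = 0; i < nvert; ++i)
    if (used[i]) roots[find(i)] = 1;
  return List::create(_["watertight"] = watertight,
                      _["components"] = (int)roots.size(),
                      _["boundary_edges"] = boundary);
}
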