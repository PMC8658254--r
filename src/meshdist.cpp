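#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Point-to-surface signed distance with angle-weighted pseudonormals
// (Baerentzen & Aanaes sign rule) over a uniform-grid triangle index.

namespace {

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator-(const V3 &o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator+(const V3 &o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
};
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
// feature: 0 face, 1..3 vertex a/b/c, 4..6 edge ab/ac/bc
V3 closest_on_tri(const V3 &p, const V3 &a, const V3 &b, const V3 &c, int &feature) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { feature = 1; return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { feature = 2; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    feature = 4;
    return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { feature = 3; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    feature = 5;
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    feature = 6;
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  feature = 0;
  return a + ab * v + ac * w;
}

struct MeshIndex {
  std::vector<V3> V;
  std::vector<std::array<int,3>> F;
  std::vector<V3> fn;                 // face normals (unit)
  std::vector<V3> vn;                 // angle-weighted vertex pseudonormals
  std::unordered_map<uint64_t, V3> en; // edge pseudonormals
  static uint64_t ekey(int a, int b) {
    return ((uint64_t)(uint32_t)std::min(a, b) << 32) |
           (uint64_t)(uint32_t)std::max(a, b);
  }
  double x0, y0, z0, cell;
  int gx, gy, gz;
  std::vector<std::vector<int>> cells;

  int cidx(int i, int j, int k) const { return (k * gy + j) * gx + i; }

  void build(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
    int nv = Vm.nrow(), nf = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = V3(Vm(i,0), Vm(i,1), Vm(i,2));
    F.resize(nf);
    fn.resize(nf);
    vn.assign(nv, V3());
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    double area_sum = 0;
    for (int f = 0; f < nf; ++f) {
      F[f] = { Fm(f,0) - 1, Fm(f,1) - 1, Fm(f,2) - 1 };
      V3 a = V[F[f][0]], b = V[F[f][1]], c = V[F[f][2]];
      V3 n = cross(b - a, c - a);
      double l = norm(n);
      area_sum += 0.5 * l;
      fn[f] = (l > 0) ? n * (1.0 / l) : V3(0, 0, 1);
      for (int e = 0; e < 3; ++e) {
        const V3 &p = V[F[f][e]];
        lo[0] = std::min(lo[0], p.x); hi[0] = std::max(hi[0], p.x);
        lo[1] = std::min(lo[1], p.y); hi[1] = std::max(hi[1], p.y);
        lo[2] = std::min(lo[2], p.z); hi[2] = std::max(hi[2], p.z);
      }
      // angle-weighted vertex normals, edge normals as adjacent-face sums
      for (int e = 0; e < 3; ++e) {
        int i0 = F[f][e], i1 = F[f][(e+1)%3], i2 = F[f][(e+2)%3];
        V3 u = V[i1] - V[i0], w = V[i2] - V[i0];
        double nu = norm(u), nw = norm(w);
        double ca = (nu > 0 && nw > 0) ? dot(u, w) / (nu * nw) : 0.0;
        ca = std::max(-1.0, std::min(1.0, ca));
        double ang = std::acos(ca);
        vn[i0] = vn[i0] + fn[f] * ang;
        uint64_t ek = ekey(i0, i1);
        en[ek] = en[ek] + fn[f];
      }
    }
    // cell size: about two mean triangle diameters, but never so fine that
    // the grid exceeds ~2e6 cells (large meshes would pay more for empty
    // cell allocation than they gain in query locality)
    double avg_tri = std::sqrt(std::max(area_sum / std::max(nf, 1), 1e-12));
    double ext_x = hi[0] - lo[0], ext_y = hi[1] - lo[1], ext_z = hi[2] - lo[2];
    double vol_bb = std::max(ext_x, 1e-6) * std::max(ext_y, 1e-6) *
                    std::max(ext_z, 1e-6);
    cell = std::max(avg_tri * 2.0, std::cbrt(vol_bb / 2e6));
    cell = std::max(cell, 1e-6);
    double pad = cell;
    x0 = lo[0] - pad; y0 = lo[1] - pad; z0 = lo[2] - pad;
    gx = std::max(1, (int)std::ceil((hi[0] - lo[0] + 2 * pad) / cell));
    gy = std::max(1, (int)std::ceil((hi[1] - lo[1] + 2 * pad) / cell));
    gz = std::max(1, (int)std::ceil((hi[2] - lo[2] + 2 * pad) / cell));
    // cap the grid so degenerate aspect ratios can't blow memory
    while ((double)gx * gy * gz > 4e6) {
      cell *= 1.5;
      gx = std::max(1, (int)std::ceil((hi[0] - lo[0] + 2 * pad) / cell));
      gy = std::max(1, (int)std::ceil((hi[1] - lo[1] + 2 * pad) / cell));
      gz = std::max(1, (int)std::ceil((hi[2] - lo[2] + 2 * pad) / cell));
    }
    cells.assign((size_t)gx * gy * gz, {});
    for (int f = 0; f < nf; ++f) {
      double flo[3] = {R_PosInf, R_PosInf, R_PosInf};
      double fhi[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int e = 0; e < 3; ++e) {
        const V3 &p = V[F[f][e]];
        flo[0] = std::min(flo[0], p.x); fhi[0] = std::max(fhi[0], p.x);
        flo[1] = std::min(flo[1], p.y); fhi[1] = std::max(fhi[1], p.y);
        flo[2] = std::min(flo[2], p.z); fhi[2] = std::max(fhi[2], p.z);
      }
      int i0 = clampi((int)((flo[0] - x0) / cell), gx);
      int i1 = clampi((int)((fhi[0] - x0) / cell), gx);
      int j0 = clampi((int)((flo[1] - y0) / cell), gy);
      int j1 = clampi((int)((fhi[1] - y0) / cell), gy);
      int k0 = clampi((int)((flo[2] - z0) / cell), gz);
      int k1 = clampi((int)((fhi[2] - z0) / cell), gz);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            cells[cidx(i, j, k)].push_back(f);
    }
  }

  static int clampi(int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); }

  // closest point over triangles in one cell
  void scan_cell(const V3 &q, int ci, int cj, int ck, double &best2,
                 V3 &bestp, int &bestf, int &bestfeat) const {
    const std::vector<int> &lst = cells[cidx(ci, cj, ck)];
    for (int f : lst) {
      int feat;
      V3 cp = closest_on_tri(q, V[F[f][0]], V[F[f][1]], V[F[f][2]], feat);
      V3 d = q - cp;
      double d2 = dot(d, d);
      if (d2 < best2) { best2 = d2; bestp = cp; bestf = f; bestfeat = feat; }
    }
  }

  void query(const V3 &q, double &sd, V3 &cp_out, int &f_out) const {
    int ci = clampi((int)((q.x - x0) / cell), gx);
    int cj = clampi((int)((q.y - y0) / cell), gy);
    int ck = clampi((int)((q.z - z0) / cell), gz);
    double best2 = R_PosInf;
    V3 bestp;
    int bestf = -1, bestfeat = 0;
    int maxr = std::max(gx, std::max(gy, gz));
    for (int r = 0; ; ++r) {
      bool any_cell = false;
      int il = ci - r, ih = ci + r, jl = cj - r, jh = cj + r,
          kl = ck - r, kh = ck + r;
      for (int k = kl; k <= kh; ++k) {
        if (k < 0 || k >= gz) continue;
        for (int j = jl; j <= jh; ++j) {
          if (j < 0 || j >= gy) continue;
          for (int i = il; i <= ih; ++i) {
            if (i < 0 || i >= gx) continue;
            bool shell = (i == il || i == ih || j == jl || j == jh ||
                          k == kl || k == kh);
            if (!shell) continue;
            any_cell = true;
            scan_cell(q, i, j, k, best2, bestp, bestf, bestfeat);
          }
        }
      }
      if (bestf >= 0) {
        // safe stop: all unvisited cells are farther than the current best
        double safe = (double)r * cell;
        if (best2 <= safe * safe) break;
      }
      if (r > maxr && bestf >= 0) break;
      if (r > 2 * maxr) break;
      (void)any_cell;
    }
    if (bestf < 0) { sd = NA_REAL; f_out = -1; return; }
    // pseudonormal by closest feature
    V3 n;
    const std::array<int,3> &fc = F[bestf];
    if (bestfeat == 0) n = fn[bestf];
    else if (bestfeat >= 1 && bestfeat <= 3) n = vn[fc[bestfeat - 1]];
    else {
      int a, b;
      if (bestfeat == 4) { a = fc[0]; b = fc[1]; }
      else if (bestfeat == 5) { a = fc[0]; b = fc[2]; }
      else { a = fc[1]; b = fc[2]; }
      auto it = en.find(ekey(a, b));
      n = (it != en.end()) ? it->second : fn[bestf];
    }
    V3 d = q - bestp;
    double dist = std::sqrt(dot(d, d));
    sd = (dot(d, n) >= 0) ? dist : -dist;
    cp_out = bestp;
    f_out = bestf;
  }
};

} // namespace

static List query_index(MeshIndex *M, const NumericMatrix &Q) {
  int n = Q.nrow();
  NumericVector d(n);
  NumericMatrix cp(n, 3);
  IntegerVector fid(n);
  for (int i = 0; i < n; ++i) {
    V3 q(Q(i,0), Q(i,1), Q(i,2)), c;
    double sd;
    int f;
    M->query(q, sd, c, f);
    d[i] = sd;
    cp(i,0) = c.x; cp(i,1) = c.y; cp(i,2) = c.z;
    fid[i] = f + 1;
  }
  return List::create(_["distance"] = d, _["closest"] = cp, _["face"] = fid);
}

// Signed distances (positive outside) and closest points for query points Q.
// [[Rcpp::export]]
List cpp_signed_distance(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  MeshIndex M;
  M.build(V, F);
  return query_index(&M, Q);
}

// Reusable spatial index (build once, query per ICP iteration).
// [[Rcpp::export]]
SEXP cpp_mesh_index(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshIndex> p(new MeshIndex(), true);
  p->build(V, F);
  return p;
}

// [[Rcpp::export]]
List cpp_mesh_index_query(SEXP xp, NumericMatrix Q) {
  XPtr<MeshIndex> p(xp);
  return query_index(p.get(), Q);
}

// Inside/outside classification of a voxel grid by ray parity along +x.
// Grid point (i,j,k) center at (x0 + i dx, y0 + j dy, z0 + k dz).
// Rays are cast along slightly offset (y,z) lines to dodge edge-exact hits.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  double x0, double dx, int nx,
                                  double y0, double dy, int ny,
                                  double z0, double dz, int nz) {
  double ey = 1.0e-4 * dy, ez = 1.4142e-4 * dz;
  std::vector<std::vector<double>> cross_x((size_t)ny * nz);
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    double ax = V(a,0), ay = V(a,1), az = V(a,2);
    double bx = V(b,0), by = V(b,1), bz = V(b,2);
    double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    double zlo = std::min(az, std::min(bz, cz)), zhi = std::max(az, std::max(bz, cz));
    int j0 = std::max(0, (int)std::ceil((ylo - ey - y0) / dy));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - ey - y0) / dy));
    int k0 = std::max(0, (int)std::ceil((zlo - ez - z0) / dz));
    int k1 = std::min(nz - 1, (int)std::floor((zhi - ez - z0) / dz));
    double d11 = by - ay, d12 = cy - ay, d21 = bz - az, d22 = cz - az;
    double det = d11 * d22 - d12 * d21;
    if (det == 0.0) continue;
    for (int k = k0; k <= k1; ++k) {
      double z = z0 + k * dz + ez;
      for (int j = j0; j <= j1; ++j) {
        double y = y0 + j * dy + ey;
        double ry = y - ay, rz = z - az;
        double u = (ry * d22 - rz * d12) / det;
        double v = (d11 * rz - d21 * ry) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double x = ax + u * (bx - ax) + v * (cx - ax);
        cross_x[(size_t)k * ny + j].push_back(x);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &cr = cross_x[(size_t)k * ny + j];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      size_t ic = 0;
      for (int i = 0; i < nx; ++i) {
        double x = x0 + i * dx;
        while (ic < cr.size() && cr[ic] < x) ++ic;
        // odd number of crossings behind the point -> inside
        out[base + i] = (ic % 2) == 1;
      }
    }
  return out;
}

// Uniform area-weighted surface sampling. `u` holds 3 deviates per sample
// (triangle pick + 2 barycentric), supplied by the caller's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_sample_surface(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix u) {
  int nf = F.nrow(), n = u.nrow();
  std::vector<double> cum(nf);
  double tot = 0;
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    V3 A(V(a,0),V(a,1),V(a,2)), B(V(b,0),V(b,1),V(b,2)), C(V(c,0),V(c,1),V(c,2));
    tot += 0.5 * norm(cross(B - A, C - A));
    cum[f] = tot;
  }
  NumericMatrix out(n, 3);
  for (int s = 0; s < n; ++s) {
    double target = u(s, 0) * tot;
    int f = (int)(std::lower_bound(cum.begin(), cum.end(), target) - cum.begin());
    if (f >= nf) f = nf - 1;
    double r1 = std::sqrt(u(s, 1)), r2 = u(s, 2);
    double wa = 1 - r1, wb = r1 * (1 - r2), wc = r1 * r2;
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    out(s,0) = wa*V(a,0) + wb*V(b,0) + wc*V(c,0);
    out(s,1) = wa*V(a,1) + wb*V(b,1) + wc*V(c,1);
    out(s,2) = wa*V(a,2) + wb*V(b,2) + wc*V(c,2);
  }
  return out;
}
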