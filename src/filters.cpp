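#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Per-slice rank-minimum filter. Slices are the (i,j) acquisition planes
// (third array dimension indexes slices); borders clamp to the slice edge,
// i.e. the window is intersected with the slice.
// [[Rcpp::export]]
NumericVector cpp_min_filter(NumericVector vol, IntegerVector dims, int window) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int h = window / 2;
  NumericVector out(vol.size());
  for (int k = 0; k < nz; ++k) {
    size_t off = (size_t)k * nx * ny;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double m = R_PosInf;
        int j0 = std::max(0, j - h), j1 = std::min(ny - 1, j + h);
        int i0 = std::max(0, i - h), i1 = std::min(nx - 1, i + h);
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii) {
            double v = vol[off + (size_t)jj * nx + ii];
            if (v < m) m = v;
          }
        out[off + (size_t)j * nx + i] = m;
      }
    }
  }
  return out;
}

namespace {
inline double sinc(double t) {
  if (t == 0.0) return 1.0;
  double pt = M_PI * t;
  return std::sin(pt) / pt;
}
}

// Separable Lanczos resampling along one axis. `outpos` gives output sample
// positions in input-index units; weights use the a-lobed windowed sinc,
// renormalized to sum to 1, with clamp-to-edge index handling.
// [[Rcpp::export]]
NumericVector cpp_lanczos_axis(NumericVector arr, IntegerVector dims, int axis,
                               NumericVector outpos, int a) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int nin = dims[axis];
  int nout = outpos.size();
  int taps = 2 * a;
  std::vector<double> W((size_t)nout * taps);
  std::vector<int> K((size_t)nout * taps);
  for (int m = 0; m < nout; ++m) {
    double u = outpos[m];
    int base = (int)std::floor(u);
    double s = 0.0;
    for (int t = 0; t < taps; ++t) {
      int k = base - a + 1 + t;
      double d = u - k;
      double w = (std::fabs(d) < a) ? sinc(d) * sinc(d / a) : 0.0;
      W[(size_t)m * taps + t] = w;
      int kc = k < 0 ? 0 : (k >= nin ? nin - 1 : k);
      K[(size_t)m * taps + t] = kc;
      s += w;
    }
    for (int t = 0; t < taps; ++t) W[(size_t)m * taps + t] /= s;
  }
  int od1 = n1, od2 = n2, od3 = n3;
  if (axis == 0) od1 = nout; else if (axis == 1) od2 = nout; else od3 = nout;
  NumericVector out((R_xlen_t)od1 * od2 * od3);
  size_t sx = 1, sy = n1, sz = (size_t)n1 * n2;
  size_t ox = 1, oy = od1, oz = (size_t)od1 * od2;
  size_t stride_in = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  // iterate over the two non-resampled axes
  int ua = (axis == 0) ? 1 : 0;
  int va = (axis == 2) ? 1 : 2;
  int nu = dims[ua], nv = dims[va];
  size_t su_in = (ua == 0) ? sx : (ua == 1) ? sy : sz;
  size_t sv_in = (va == 0) ? sx : (va == 1) ? sy : sz;
  size_t su_out = (ua == 0) ? ox : (ua == 1) ? oy : oz;
  size_t sv_out = (va == 0) ? ox : (va == 1) ? oy : oz;
  size_t so_out = (axis == 0) ? ox : (axis == 1) ? oy : oz;
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      size_t bin = (size_t)u * su_in + (size_t)v * sv_in;
      size_t bout = (size_t)u * su_out + (size_t)v * sv_out;
      for (int m = 0; m < nout; ++m) {
        double acc = 0.0;
        size_t wt = (size_t)m * taps;
        for (int t = 0; t < taps; ++t)
          acc += W[wt + t] * arr[bin + (size_t)K[wt + t] * stride_in];
        out[bout + (size_t)m * so_out] = acc;
      }
    }
  }
  out.attr("odims") = IntegerVector::create(od1, od2, od3);
  return out;
}

namespace {
void neighbour_offsets(int connectivity, std::vector<std::array<int,3>> &off) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nman = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nman == 0) continue;
        if (connectivity == 6 && nman != 1) continue;
        off.push_back({dx, dy, dz});
      }
}
}

// Union of connected components of `mask` containing at least one seed.
// Seeds are 0-based voxel indices (n x 3).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(LogicalVector mask, IntegerVector dims,
                              IntegerMatrix seeds, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  LogicalVector out(mask.size());
  std::vector<char> visited(mask.size(), 0);
  std::queue<std::array<int,3>> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      stop("seed outside the volume");
    size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
    if (mask[idx] && !visited[idx]) {
      visited[idx] = 1;
      out[idx] = true;
      q.push({i, j, k});
    }
  }
  while (!q.empty()) {
    auto p = q.front(); q.pop();
    for (auto &d : off) {
      int i = p[0] + d[0], j = p[1] + d[1], k = p[2] + d[2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
      if (!mask[idx] || visited[idx]) continue;
      visited[idx] = 1;
      out[idx] = true;
      q.push({i, j, k});
    }
  }
  return out;
}

// 26-neighbourhood binary dilation (one step).
// [[Rcpp::export]]
LogicalVector cpp_dilate_mask(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
        if (!mask[idx]) continue;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              out[(size_t)kk * nx * ny + (size_t)jj * nx + ii] = true;
            }
      }
  return out;
}

// Largest connected component of a boolean mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims,
                                    int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  std::vector<int> label(mask.size(), 0);
  int nlab = 0;
  std::vector<size_t> count(1, 0);
  std::queue<std::array<int,3>> q;
  for (size_t start = 0; start < (size_t)mask.size(); ++start) {
    if (!mask[start] || label[start]) continue;
    ++nlab;
    count.push_back(0);
    int si = (int)(start % nx);
    int sj = (int)((start / nx) % ny);
    int sk = (int)(start / ((size_t)nx * ny));
    label[start] = nlab; count[nlab]++;
    q.push({si, sj, sk});
    while (!q.empty()) {
      auto p = q.front(); q.pop();
      for (auto &d : off) {
        int i = p[0] + d[0], j = p[1] + d[1], k = p[2] + d[2];
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
        if (!mask[idx] || label[idx]) continue;
        label[idx] = nlab; count[nlab]++;
        q.push({i, j, k});
      }
    }
  }
  int best = 0;
  for (int l = 1; l <= nlab; ++l) if (count[l] > count[best]) best = l;
  LogicalVector out(mask.size());
  if (best > 0)
    for (size_t v = 0; v < (size_t)mask.size(); ++v) out[v] = (label[v] == best);
  return out;
}
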