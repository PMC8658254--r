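#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Analytic signed distance of the phantom solid: a tube swept along a dense
// polyline (mandibular body arc) unioned with capsules (rami) and spheres
// (condyles). Negative inside. Exact up to the polyline chord error.
// [[Rcpp::export]]
NumericVector cpp_sdf_points(NumericMatrix pts, NumericMatrix polyline,
                             double tube_r, NumericMatrix capsules,
                             NumericMatrix spheres) {
  int n = pts.nrow();
  int nseg = polyline.nrow() - 1;
  int ncap = capsules.nrow();
  int nsph = spheres.nrow();
  // hoist segment geometry out of the per-point loop
  std::vector<double> sax(std::max(nseg, 0)), say(sax.size()), saz(sax.size()),
      sux(sax.size()), suy(sax.size()), suz(sax.size()), sinv(sax.size());
  for (int s = 0; s < nseg; ++s) {
    sax[s] = polyline(s, 0); say[s] = polyline(s, 1); saz[s] = polyline(s, 2);
    sux[s] = polyline(s + 1, 0) - sax[s];
    suy[s] = polyline(s + 1, 1) - say[s];
    suz[s] = polyline(s + 1, 2) - saz[s];
    double uu = sux[s] * sux[s] + suy[s] * suy[s] + suz[s] * suz[s];
    sinv[s] = uu > 0 ? 1.0 / uu : 0.0;
  }
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double px = pts(p,0), py = pts(p,1), pz = pts(p,2);
    double d = R_PosInf;
    if (nseg >= 1) {
      double best2 = R_PosInf;
      for (int s = 0; s < nseg; ++s) {
        double wx = px-sax[s], wy = py-say[s], wz = pz-saz[s];
        double t = (wx*sux[s]+wy*suy[s]+wz*suz[s])*sinv[s];
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double dx = wx - t*sux[s], dy = wy - t*suy[s], dz = wz - t*suz[s];
        double d2 = dx*dx+dy*dy+dz*dz;
        if (d2 < best2) best2 = d2;
      }
      d = std::sqrt(best2) - tube_r;
    }
    for (int c = 0; c < ncap; ++c) {
      double ax = capsules(c,0), ay = capsules(c,1), az = capsules(c,2);
      double bx = capsules(c,3), by = capsules(c,4), bz = capsules(c,5);
      double r = capsules(c,6);
      double ux = bx-ax, uy = by-ay, uz = bz-az;
      double wx = px-ax, wy = py-ay, wz = pz-az;
      double uu = ux*ux+uy*uy+uz*uz;
      double t = uu > 0 ? (wx*ux+wy*uy+wz*uz)/uu : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = wx - t*ux, dy = wy - t*uy, dz = wz - t*uz;
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz) - r;
      if (dc < d) d = dc;
    }
    for (int s = 0; s < nsph; ++s) {
      double dx = px - spheres(s,0), dy = py - spheres(s,1), dz = pz - spheres(s,2);
      double ds = std::sqrt(dx*dx+dy*dy+dz*dz) - spheres(s,3);
      if (ds < d) d = ds;
    }
    out[p] = d;
  }
  return out;
}

// Even-odd point-in-polygon test; points on an edge count as inside.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  LogicalVector out(n);
  double eps = 1e-9;
  for (int p = 0; p < n; ++p) {
    double x = pts(p,0), y = pts(p,1);
    bool inside = false, boundary = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double xi = poly(i,0), yi = poly(i,1);
      double xj = poly(j,0), yj = poly(j,1);
      // on-segment check
      double crossv = (xj - xi) * (y - yi) - (x - xi) * (yj - yi);
      double d2 = (xj-xi)*(xj-xi)+(yj-yi)*(yj-yi);
      if (d2 > 0 && std::fabs(crossv) <= eps * std::sqrt(d2)) {
        double t = ((x - xi)*(xj - xi) + (y - yi)*(yj - yi)) / d2;
        if (t >= -eps && t <= 1 + eps) { boundary = true; break; }
      }
      if (((yi > y) != (yj > y))) {
        double xint = xi + (y - yi) / (yj - yi) * (xj - xi);
        if (x < xint) inside = !inside;
      }
    }
    out[p] = boundary || inside;
  }
  return out;
}

// Minimum distance from 2-D points to a polyline (open or closed).
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline2d(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p,0), y = pts(p,1);
    double best2 = R_PosInf;
    for (int s = 0; s < m - 1; ++s) {
      double ax = poly(s,0), ay = poly(s,1);
      double bx = poly(s+1,0), by = poly(s+1,1);
      double ux = bx-ax, uy = by-ay;
      double uu = ux*ux+uy*uy;
      double t = uu > 0 ? ((x-ax)*ux+(y-ay)*uy)/uu : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = x-ax-t*ux, dy = y-ay-t*uy;
      double d2 = dx*dx+dy*dy;
      if (d2 < best2) best2 = d2;
    }
    out[p] = std::sqrt(best2);
  }
  return out;
}
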