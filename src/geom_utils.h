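#ifndef IDIOLOC_GEOM_UTILS_H
#define IDIOLOC_GEOM_UTILS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Polygon rings of an arena: rings[0] is the outer boundary, the rest are
// voids. Traversable = inside outer and outside every void (even-odd).
struct RingSet {
  std::vector<std::vector<double> > x, y;
  explicit RingSet(const Rcpp::List& rings) {
    int m = rings.size();
    x.resize(m); y.resize(m);
    for (int r = 0; r < m; ++r) {
      Rcpp::NumericMatrix ring = rings[r];
      int n = ring.nrow();
      x[r].resize(n); y[r].resize(n);
      for (int i = 0; i < n; ++i) { x[r][i] = ring(i, 0); y[r][i] = ring(i, 1); }
    }
  }
};

inline bool point_in_ring(double px, double py,
                          const std::vector<double>& x,
                          const std::vector<double>& y) {
  int n = (int)x.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]))
      inside = !inside;
  }
  return inside;
}

inline bool point_traversable(double px, double py, const RingSet& rs) {
  if (rs.x.empty()) return true;
  if (!point_in_ring(px, py, rs.x[0], rs.y[0])) return false;
  for (size_t r = 1; r < rs.x.size(); ++r)
    if (point_in_ring(px, py, rs.x[r], rs.y[r])) return false;
  return true;
}

inline double cross3(double ax, double ay, double bx, double by,
                     double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// Does segment p0-p1 intersect segment a-b?  Touching counts as crossing.
inline bool seg_seg_cross(double p0x, double p0y, double p1x, double p1y,
                          double ax, double ay, double bx, double by) {
  double d1 = cross3(ax, ay, bx, by, p0x, p0y);
  double d2 = cross3(ax, ay, bx, by, p1x, p1y);
  double d3 = cross3(p0x, p0y, p1x, p1y, ax, ay);
  double d4 = cross3(p0x, p0y, p1x, p1y, bx, by);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  // collinear / endpoint-touch cases
  if (d1 == 0 && std::min(ax, bx) <= p0x && p0x <= std::max(ax, bx) &&
      std::min(ay, by) <= p0y && p0y <= std::max(ay, by)) return true;
  if (d2 == 0 && std::min(ax, bx) <= p1x && p1x <= std::max(ax, bx) &&
      std::min(ay, by) <= p1y && p1y <= std::max(ay, by)) return true;
  if (d3 == 0 && std::min(p0x, p1x) <= ax && ax <= std::max(p0x, p1x) &&
      std::min(p0y, p1y) <= ay && ay <= std::max(p0y, p1y)) return true;
  if (d4 == 0 && std::min(p0x, p1x) <= bx && bx <= std::max(p0x, p1x) &&
      std::min(p0y, p1y) <= by && by <= std::max(p0y, p1y)) return true;
  return false;
}

// Fractional position along p0->p1 of the crossing with a-b, or -1 if none.
inline double seg_seg_cross_param(double p0x, double p0y, double p1x, double p1y,
                                  double ax, double ay, double bx, double by) {
  if (!seg_seg_cross(p0x, p0y, p1x, p1y, ax, ay, bx, by)) return -1.0;
  double d1 = cross3(ax, ay, bx, by, p0x, p0y);
  double d2 = cross3(ax, ay, bx, by, p1x, p1y);
  double denom = d1 - d2;
  if (denom == 0) return 0.0;  // collinear overlap: treat as immediate
  double t = d1 / denom;
  if (t < 0) t = 0; if (t > 1) t = 1;
  return t;
}

inline double pt_seg_dist2(double px, double py, double ax, double ay,
                           double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = (L2 > 0) ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
  if (t < 0) t = 0; if (t > 1) t = 1;
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

// Edge table: rows (ax, ay, bx, by), includes outer boundary, voids, barriers.
struct EdgeSet {
  std::vector<double> ax, ay, bx, by;
  explicit EdgeSet(const Rcpp::NumericMatrix& e) {
    int n = e.nrow();
    ax.resize(n); ay.resize(n); bx.resize(n); by.resize(n);
    for (int i = 0; i < n; ++i) {
      ax[i] = e(i, 0); ay[i] = e(i, 1); bx[i] = e(i, 2); by[i] = e(i, 3);
    }
  }
  int size() const { return (int)ax.size(); }
};

// Uniform-grid spatial index over edges: for each cell, ids of edges whose
// distance from the cell centre is at most `reach` (built in R/C++ once per
// arena).  A query from any point in the cell returns every edge within
// (reach - cell_diag/2) of that point; empty cells imply "far from all
// boundaries", which is the common fast path for interior particles.
struct EdgeIndex {
  double x0, y0, h;
  int nx, ny;
  double reach;
  std::vector<int> start;  // nx*ny + 1
  std::vector<int> ids;
  bool valid;
  EdgeIndex() : valid(false) {}
  explicit EdgeIndex(const Rcpp::List& idx) {
    valid = idx.size() > 0;
    if (!valid) return;
    x0 = Rcpp::as<double>(idx["x0"]);
    y0 = Rcpp::as<double>(idx["y0"]);
    h  = Rcpp::as<double>(idx["h"]);
    nx = Rcpp::as<int>(idx["nx"]);
    ny = Rcpp::as<int>(idx["ny"]);
    reach = Rcpp::as<double>(idx["reach"]);
    Rcpp::IntegerVector s = idx["cell_start"];
    Rcpp::IntegerVector e = idx["cell_edges"];
    start.assign(s.begin(), s.end());
    ids.assign(e.begin(), e.end());
  }
  // cell index for a point (clamped to grid)
  inline int cell(double px, double py) const {
    int ix = (int)std::floor((px - x0) / h);
    int iy = (int)std::floor((py - y0) / h);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    return iy * nx + ix;
  }
};

#endif
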