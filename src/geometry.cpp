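#include "geom_utils.h"
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_points_in_rings(NumericVector x, NumericVector y, List rings) {
  RingSet rs(rings);
  int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = point_traversable(x[i], y[i], rs);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_segments_cross(NumericVector x0, NumericVector y0,
                                 NumericVector x1, NumericVector y1,
                                 NumericMatrix edges) {
  EdgeSet es(edges);
  int n = x0.size(), m = es.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool hit = false;
    for (int j = 0; j < m && !hit; ++j)
      hit = seg_seg_cross(x0[i], y0[i], x1[i], y1[i],
                          es.ax[j], es.ay[j], es.bx[j], es.by[j]);
    out[i] = hit;
  }
  return out;
}

// Earliest crossing parameter in [0,1] for each segment, or -1 when clear.
// [[Rcpp::export]]
NumericVector cpp_segments_cross_param(NumericVector x0, NumericVector y0,
                                       NumericVector x1, NumericVector y1,
                                       NumericMatrix edges) {
  EdgeSet es(edges);
  int n = x0.size(), m = es.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double tmin = -1.0;
    for (int j = 0; j < m; ++j) {
      double t = seg_seg_cross_param(x0[i], y0[i], x1[i], y1[i],
                                     es.ax[j], es.ay[j], es.bx[j], es.by[j]);
      if (t >= 0 && (tmin < 0 || t < tmin)) tmin = t;
    }
    out[i] = tmin;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_edge_dist(NumericVector x, NumericVector y,
                                NumericMatrix edges) {
  EdgeSet es(edges);
  int n = x.size(), m = es.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d2 = pt_seg_dist2(x[i], y[i], es.ax[j], es.ay[j], es.bx[j], es.by[j]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Mean Euclidean distance from each query point to a cloud of points
// (used for the uniform-distance normalizer of the place stability index).
// [[Rcpp::export]]
NumericVector cpp_mean_dist(NumericVector qx, NumericVector qy,
                            NumericVector px, NumericVector py) {
  int nq = qx.size(), np = px.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double s = 0.0;
    for (int j = 0; j < np; ++j) {
      double dx = px[j] - qx[i], dy = py[j] - qy[i];
      s += std::sqrt(dx * dx + dy * dy);
    }
    out[i] = s / np;
  }
  return out;
}

// Build a uniform-grid edge index: cell lists hold ids (0-based) of edges
// within `reach` of the cell centre.
// [[Rcpp::export]]
List cpp_build_edge_index(NumericMatrix edges, double x0, double y0,
                          double h, int nx, int ny, double reach) {
  EdgeSet es(edges);
  int m = es.size(), ncell = nx * ny;
  double r2 = reach * reach;
  std::vector<std::vector<int> > cells(ncell);
  for (int iy = 0; iy < ny; ++iy) {
    double cy = y0 + (iy + 0.5) * h;
    for (int ix = 0; ix < nx; ++ix) {
      double cx = x0 + (ix + 0.5) * h;
      std::vector<int>& lst = cells[iy * nx + ix];
      for (int j = 0; j < m; ++j)
        if (pt_seg_dist2(cx, cy, es.ax[j], es.ay[j], es.bx[j], es.by[j]) <= r2)
          lst.push_back(j);
    }
  }
  IntegerVector start(ncell + 1);
  int total = 0;
  for (int c = 0; c < ncell; ++c) { start[c] = total; total += cells[c].size(); }
  start[ncell] = total;
  IntegerVector ids(total);
  int k = 0;
  for (int c = 0; c < ncell; ++c)
    for (size_t i = 0; i < cells[c].size(); ++i) ids[k++] = cells[c][i];
  return List::create(_["x0"] = x0, _["y0"] = y0, _["h"] = h,
                      _["nx"] = nx, _["ny"] = ny, _["reach"] = reach,
                      _["cell_start"] = start, _["cell_edges"] = ids);
}
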