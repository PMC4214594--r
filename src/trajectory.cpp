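#include "geom_utils.h"
using namespace Rcpp;

namespace {

struct BodyT {
  std::vector<double> bx, by;
  double radius;
  explicit BodyT(const NumericMatrix& b) : radius(0.0) {
    for (int i = 0; i < b.nrow(); ++i) {
      bx.push_back(b(i, 0)); by.push_back(b(i, 1));
      double r = std::sqrt(b(i, 0) * b(i, 0) + b(i, 1) * b(i, 1));
      if (r > radius) radius = r;
    }
  }
  int size() const { return (int)bx.size(); }
};

// earliest crossing parameter for the swept body (centre + perimeter points),
// testing against all edges (truth generation is not the hot path)
double sweep_param(const EdgeSet& es, const BodyT& body,
                   double x0, double y0, double th0,
                   double x1, double y1, double th1) {
  int m = es.size();
  double tmin = -1.0;
  for (int j = 0; j < m; ++j) {
    double t = seg_seg_cross_param(x0, y0, x1, y1,
                                   es.ax[j], es.ay[j], es.bx[j], es.by[j]);
    if (t >= 0 && (tmin < 0 || t < tmin)) tmin = t;
  }
  int K = body.size();
  if (K > 0) {
    double c0 = std::cos(th0), s0 = std::sin(th0);
    double c1 = std::cos(th1), s1 = std::sin(th1);
    for (int k = 0; k < K; ++k) {
      double ax = x0 + c0 * body.bx[k] - s0 * body.by[k];
      double ay = y0 + s0 * body.bx[k] + c0 * body.by[k];
      double bx = x1 + c1 * body.bx[k] - s1 * body.by[k];
      double by = y1 + s1 * body.bx[k] + c1 * body.by[k];
      for (int j = 0; j < m; ++j) {
        double t = seg_seg_cross_param(ax, ay, bx, by,
                                       es.ax[j], es.ay[j], es.bx[j], es.by[j]);
        if (t >= 0 && (tmin < 0 || t < tmin)) tmin = t;
      }
    }
  }
  return tmin;
}

double wrap_2pi(double a) {
  const double two_pi = 2.0 * M_PI;
  return a - std::floor(a / two_pi) * two_pi;
}

inline double wrap_pi_t(double a) {
  const double two_pi = 2.0 * M_PI;
  a = (a + M_PI) - std::floor((a + M_PI) / two_pi) * two_pi;
  return a - M_PI;
}

}  // namespace

// Generate a true trajectory inside an arena.
// policy: 0 = correlated random walk, 1 = thigmotactic (wall following)
// outer_edges: edges of the outer boundary only (used for wall steering);
// edges: all boundary edges (outer + voids + barriers) for collision.
// Returns (n_steps + 1) x 3 matrix of poses.
// [[Rcpp::export]]
NumericMatrix cpp_gen_traj(List rings, NumericMatrix edges,
                           NumericMatrix outer_edges,
                           NumericMatrix body_pts,
                           int n_steps, double dt,
                           double speed_mean, double speed_sd,
                           double turn_sd, int policy,
                           double wall_offset, double steer_gain,
                           double x0, double y0, double th0) {
  RNGScope scope;
  RingSet rs(rings);
  EdgeSet es(edges);
  EdgeSet wall(outer_edges);
  BodyT body(body_pts);

  // thigmotaxis steers the body surface (not the centre) to wall_offset:
  // add the lateral half-width plus a curvature allowance for the tips of
  // an elongated body
  double amax = 0.0, bmax = 0.0;
  for (int k = 0; k < body.size(); ++k) {
    amax = std::max(amax, std::fabs(body.bx[k]));
    bmax = std::max(bmax, std::fabs(body.by[k]));
  }
  double center_offset = wall_offset + bmax + 0.15 * amax;

  NumericMatrix out(n_steps + 1, 3);
  double x = x0, y = y0, th = wrap_2pi(th0);
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = th;
  int tangent_sign = (unif_rand() < 0.5) ? 1 : -1;
  bool pending_redraw = false;

  for (int s = 1; s <= n_steps; ++s) {
    double th_new;
    if (pending_redraw) {
      // after a wall encounter: redraw the heading uniformly among inward
      // directions (so each step's displacement stays collinear with the
      // end-of-step heading, keeping dead reckoning exact at zero noise)
      pending_redraw = false;
      bool ok = false;
      double cand = th;
      for (int attempt = 0; attempt < 100 && !ok; ++attempt) {
        cand = unif_rand() * 2.0 * M_PI;
        double probe = 2.0;
        double px = x + probe * std::cos(cand);
        double py = y + probe * std::sin(cand);
        if (sweep_param(es, body, x, y, th, px, py, cand) < 0 &&
            point_traversable(px, py, rs))
          ok = true;
      }
      th_new = cand;
      if (!ok) pending_redraw = true;  // trapped: retry next step
    } else if (policy == 1) {
      // steer along the nearest outer wall at wall_offset
      double best = R_PosInf;
      int je = 0;
      for (int j = 0; j < wall.size(); ++j) {
        double d2 = pt_seg_dist2(x, y, wall.ax[j], wall.ay[j], wall.bx[j], wall.by[j]);
        if (d2 < best) { best = d2; je = j; }
      }
      double d = std::sqrt(best);
      double ex = wall.bx[je] - wall.ax[je], ey = wall.by[je] - wall.ay[je];
      double el = std::sqrt(ex * ex + ey * ey);
      ex /= el; ey /= el;
      double tx = tangent_sign * ex, ty = tangent_sign * ey;
      // outward normal approximation: direction from agent to closest point
      double L2 = el * el;
      double tt = ((x - wall.ax[je]) * ex * el + (y - wall.ay[je]) * ey * el) / L2;
      if (tt < 0) tt = 0; if (tt > 1) tt = 1;
      double cxp = wall.ax[je] + tt * ex * el, cyp = wall.ay[je] + tt * ey * el;
      double nx = cxp - x, ny = cyp - y;
      double nl = std::sqrt(nx * nx + ny * ny);
      if (nl > 1e-9) { nx /= nl; ny /= nl; }
      double corr = steer_gain * (d - center_offset);
      if (corr > 0.8) corr = 0.8; if (corr < -0.8) corr = -0.8;
      double vx = tx + corr * nx, vy = ty + corr * ny;
      double desired = std::atan2(vy, vx);
      double dturn = wrap_pi_t(desired - th);
      double max_turn = 1.2;
      if (dturn > max_turn) dturn = max_turn;
      if (dturn < -max_turn) dturn = -max_turn;
      th_new = th + dturn + norm_rand() * 0.05;
    } else {
      th_new = th + norm_rand() * turn_sd;
    }
    th_new = wrap_2pi(th_new);
    double speed = speed_mean + (speed_sd > 0 ? norm_rand() * speed_sd : 0.0);
    if (speed < 0) speed = 0;
    double step = speed * dt;
    double x1 = x + step * std::cos(th_new);
    double y1 = y + step * std::sin(th_new);

    double tcross = sweep_param(es, body, x, y, th, x1, y1, th_new);
    if (tcross >= 0) {
      // truncate just short of the wall; the inward redraw happens at the
      // start of the next step so heading and displacement stay collinear
      double margin = (step > 0) ? std::max(0.0, tcross - 1.0 / std::max(step, 1e-9)) : 0.0;
      double keep = margin * 0.95;
      x1 = x + keep * step * std::cos(th_new);
      y1 = y + keep * step * std::sin(th_new);
      // the sweep tested the full-length motion; re-check the truncated
      // pose (rotation alone can push a body tip out near a wall) and
      // reject the whole step if the body no longer fits
      bool fits = point_traversable(x1, y1, rs);
      if (fits && body.size() > 0) {
        double c1 = std::cos(th_new), s1 = std::sin(th_new);
        for (int k = 0; k < body.size() && fits; ++k) {
          double bx = x1 + c1 * body.bx[k] - s1 * body.by[k];
          double by = y1 + s1 * body.bx[k] + c1 * body.by[k];
          fits = point_traversable(bx, by, rs);
        }
      }
      if (!fits) { x1 = x; y1 = y; th_new = th; }
      // random policy: redraw an inward heading next step; thigmotaxis
      // recovers through its wall steering instead (smoother, trackable)
      pending_redraw = (policy == 0);
    }
    x = x1; y = y1; th = th_new;
    out(s, 0) = x; out(s, 1) = y; out(s, 2) = th;
  }
  return out;
}
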