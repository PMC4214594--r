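#include "geom_utils.h"
using namespace Rcpp;

namespace {

struct Body {
  std::vector<double> bx, by;  // offsets in body frame
  double radius;
  explicit Body(const NumericMatrix& b) : radius(0.0) {
    for (int i = 0; i < b.nrow(); ++i) {
      bx.push_back(b(i, 0)); by.push_back(b(i, 1));
      double r = std::sqrt(b(i, 0) * b(i, 0) + b(i, 1) * b(i, 1));
      if (r > radius) radius = r;
    }
  }
  int size() const { return (int)bx.size(); }
};

// coarse lookup of distance-to-nearest-boundary (lower bound via the
// Lipschitz property: true distance >= grid value - cell diagonal / 2)
struct DistGrid {
  double x0, y0, cell, margin;
  int nx, ny;
  std::vector<double> d;
  bool valid;
  DistGrid() : valid(false) {}
  explicit DistGrid(const Rcpp::List& dg) {
    valid = dg.size() > 0;
    if (!valid) return;
    x0 = Rcpp::as<double>(dg["x0"]);
    y0 = Rcpp::as<double>(dg["y0"]);
    cell = Rcpp::as<double>(dg["cell"]);
    Rcpp::NumericMatrix m = dg["d"];
    nx = m.nrow(); ny = m.ncol();
    d.assign(m.begin(), m.end());
    margin = cell * 0.7072;
  }
  // conservative lower bound on distance from (px, py) to any boundary
  inline double lower_bound(double px, double py) const {
    int ix = (int)std::floor((px - x0) / cell);
    int iy = (int)std::floor((py - y0) / cell);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return 0.0;
    return d[iy * nx + ix] - margin;
  }
};

class Cull {
public:
  Cull(const EdgeSet& es, const EdgeIndex& idx, const Body& body,
       const DistGrid& dgrid)
    : es_(es), idx_(idx), body_(body), dgrid_(dgrid) {
    usable_ = idx_.valid ? idx_.reach - idx_.h * 0.7072 : 0.0;
  }

  // candidate edges near (x, y); returns false if brute force is required
  bool candidates(double x, double y, double extent,
                  const int*& ids, int& n) const {
    if (!idx_.valid || extent > usable_) return false;
    int c = idx_.cell(x, y);
    n = idx_.start[c + 1] - idx_.start[c];
    ids = n > 0 ? &idx_.ids[idx_.start[c]] : NULL;
    return true;
  }

  bool path_crosses(double x0, double y0, double th0,
                    double x1, double y1, double th1, double steplen) const {
    double extent = steplen + body_.radius;
    // fast path: whole swept body provably clear of every boundary
    if (dgrid_.valid && dgrid_.lower_bound(x0, y0) > extent) return false;
    const int* ids = NULL; int n = 0;
    bool indexed = candidates(x0, y0, extent, ids, n);
    int m = indexed ? n : es_.size();
    if (m == 0) return false;
    if (seg_hits(x0, y0, x1, y1, indexed, ids, m)) return true;
    int K = body_.size();
    if (K > 0) {
      double c0 = std::cos(th0), s0 = std::sin(th0);
      double c1 = std::cos(th1), s1 = std::sin(th1);
      for (int k = 0; k < K; ++k) {
        double ax = x0 + c0 * body_.bx[k] - s0 * body_.by[k];
        double ay = y0 + s0 * body_.bx[k] + c0 * body_.by[k];
        double bx = x1 + c1 * body_.bx[k] - s1 * body_.by[k];
        double by = y1 + s1 * body_.bx[k] + c1 * body_.by[k];
        if (seg_hits(ax, ay, bx, by, indexed, ids, m)) return true;
      }
    }
    return false;
  }

  bool endpoint_outside(double x1, double y1, double th1,
                        const RingSet& rs) const {
    if (!point_traversable(x1, y1, rs)) return true;
    int K = body_.size();
    if (K > 0) {
      double c1 = std::cos(th1), s1 = std::sin(th1);
      for (int k = 0; k < K; ++k) {
        double bx = x1 + c1 * body_.bx[k] - s1 * body_.by[k];
        double by = y1 + s1 * body_.bx[k] + c1 * body_.by[k];
        if (!point_traversable(bx, by, rs)) return true;
      }
    }
    return false;
  }

  // min distance from body perimeter (or centre) to any boundary edge;
  // capped at `cap` (returns cap when all edges are farther than the index
  // reach guarantees)
  double boundary_dist(double x, double y, double th, double cap) const {
    const int* ids = NULL; int n = 0;
    bool indexed = candidates(x, y, body_.radius, ids, n);
    int m = indexed ? n : es_.size();
    if (m == 0) return cap;
    double best = cap * cap;
    int K = body_.size();
    for (int j = 0; j < m; ++j) {
      int e = indexed ? ids[j] : j;
      double d2 = pt_seg_dist2(x, y, es_.ax[e], es_.ay[e], es_.bx[e], es_.by[e]);
      if (K > 0) {
        double c = std::cos(th), s = std::sin(th);
        for (int k = 0; k < K; ++k) {
          double px = x + c * body_.bx[k] - s * body_.by[k];
          double py = y + s * body_.bx[k] + c * body_.by[k];
          double dk = pt_seg_dist2(px, py, es_.ax[e], es_.ay[e], es_.bx[e], es_.by[e]);
          if (dk < d2) d2 = dk;
        }
      }
      if (d2 < best) best = d2;
    }
    return std::sqrt(best);
  }

private:
  bool seg_hits(double x0, double y0, double x1, double y1,
                bool indexed, const int* ids, int m) const {
    for (int j = 0; j < m; ++j) {
      int e = indexed ? ids[j] : j;
      if (seg_seg_cross(x0, y0, x1, y1, es_.ax[e], es_.ay[e], es_.bx[e], es_.by[e]))
        return true;
    }
    return false;
  }
  const EdgeSet& es_;
  const EdgeIndex& idx_;
  const Body& body_;
  const DistGrid& dgrid_;
  double usable_;
};

void systematic_resample(std::vector<double>& x, std::vector<double>& y,
                         std::vector<double>& th, std::vector<int>& anc,
                         const std::vector<double>& w, double W) {
  int N = (int)x.size();
  std::vector<double> nx(N), ny(N), nth(N);
  std::vector<int> nanc(N);
  double u = unif_rand() / N;
  int j = 0;
  double cum = w[0] / W;
  for (int i = 0; i < N; ++i) {
    double target = u + (double)i / N;
    while (cum < target && j < N - 1) { ++j; cum += w[j] / W; }
    nx[i] = x[j]; ny[i] = y[j]; nth[i] = th[j]; nanc[i] = anc[j];
  }
  x.swap(nx); y.swap(ny); th.swap(nth); anc.swap(nanc);
}

inline double wrap_pi(double a) {
  const double two_pi = 2.0 * M_PI;
  a = (a + M_PI) - std::floor((a + M_PI) / two_pi) * two_pi;
  return a - M_PI;
}

}  // namespace

// Run the boundary-culling particle filter over a whole displacement stream.
//
// init: N x 3 (x, y, theta); anc0: ancestor labels (1-based; NA allowed)
// dhead: per-step heading change (iPI) or absolute heading (aPI)
// steps: per-step reported step length
// boundary_mode: 0 = none, 1 = discrete endpoint, 2 = crossing
// truth: (T+1) x >=2 true positions (col 1-2) for metric recording (may be
//        0-row); in reverse mode row T-s is used after s backward steps.
// reinit_pool: points to reinitialize from after a total cull.
// compass_obs / contact_obs: per-step observations (NaN = absent).
// [[Rcpp::export]]
List cpp_pf_run(NumericMatrix init, IntegerVector anc0,
                NumericVector dhead, NumericVector steps,
                bool api, bool reverse,
                double sig_th, double sig_step,
                int boundary_mode,
                List rings, NumericMatrix edges, List edge_index,
                List dist_grid,
                NumericMatrix body_pts,
                NumericMatrix truth,
                int record_every, bool record_lineage,
                NumericMatrix reinit_pool,
                NumericVector compass_obs, double compass_sd,
                NumericVector contact_obs, double contact_tol) {
  RNGScope scope;
  const int N = init.nrow();
  const int T = dhead.size();
  RingSet rs(rings);
  EdgeSet es(edges);
  EdgeIndex idx(edge_index);
  DistGrid dgrid(dist_grid);
  Body body(body_pts);
  Cull cull(es, idx, body, dgrid);

  std::vector<double> x(N), y(N), th(N), w(N, 1.0);
  std::vector<int> anc(N);
  for (int i = 0; i < N; ++i) {
    x[i] = init(i, 0); y[i] = init(i, 1); th[i] = init(i, 2);
    anc[i] = anc0[i];
  }

  const bool has_truth = truth.nrow() > 0;
  const bool has_compass = compass_obs.size() == T;
  const bool has_contact = contact_obs.size() == T;
  const int M = reinit_pool.nrow();

  // record bookkeeping
  std::vector<int> rec_steps;
  for (int s = record_every; s <= T; s += record_every) rec_steps.push_back(s);
  if (rec_steps.empty() || rec_steps.back() != T) rec_steps.push_back(T);
  int nrec = (int)rec_steps.size();
  NumericVector dpost(nrec, NA_REAL), hc(nrec), hs(nrec), mx(nrec), my(nrec);
  IntegerMatrix lineage(record_lineage ? nrec : 0, record_lineage ? N : 0);
  int rec_i = 0, n_reinit = 0, n_compass_degen = 0;

  for (int s = 1; s <= T; ++s) {
    int sidx = reverse ? (T - s) : (s - 1);
    double dh = dhead[sidx], sl = steps[sidx];
    bool any_dead = false;

    for (int i = 0; i < N; ++i) {
      double th_new, step_i = sl * (1.0 + (sig_step > 0 ? norm_rand() * sig_step : 0.0));
      if (step_i < 0) step_i = 0;
      double x0 = x[i], y0 = y[i], th_old = th[i];
      double x1, y1;
      if (!reverse) {
        th_new = api ? dh : th_old + dh;
        if (sig_th > 0) th_new += norm_rand() * sig_th;
        x1 = x0 + step_i * std::cos(th_new);
        y1 = y0 + step_i * std::sin(th_new);
      } else {
        // undo step s: move back along the heading held during that step,
        // then undo the heading change
        double th_move = api ? dh : th_old;
        if (api && sig_th > 0) th_move += norm_rand() * sig_th;
        x1 = x0 - step_i * std::cos(th_move);
        y1 = y0 - step_i * std::sin(th_move);
        if (api) {
          th_new = th_move;
        } else {
          th_new = th_old - dh;
          if (sig_th > 0) th_new += norm_rand() * sig_th;
        }
      }
      bool dead = false;
      if (boundary_mode == 2) {
        dead = cull.path_crosses(x0, y0, th_old, x1, y1, th_new, step_i);
      } else if (boundary_mode == 1) {
        dead = cull.endpoint_outside(x1, y1, th_new, rs);
      }
      x[i] = x1; y[i] = y1; th[i] = th_new;
      if (dead) { w[i] = 0.0; any_dead = true; }
    }

    // contact observation: cull particles inconsistent with the flag
    if (has_contact && !ISNAN(contact_obs[sidx])) {
      bool in_contact = contact_obs[sidx] > 0.5;
      double cap = contact_tol * 2.0 + 1.0;
      for (int i = 0; i < N; ++i) {
        if (w[i] <= 0) continue;
        double d = cull.boundary_dist(x[i], y[i], th[i], cap);
        bool near = d <= contact_tol;
        if (near != in_contact) { w[i] = 0.0; any_dead = true; }
      }
    }

    // compass observation: circular-normal likelihood reweighting
    bool reweighted = false;
    if (has_compass && !ISNAN(compass_obs[sidx])) {
      double obs = compass_obs[sidx];
      double inv2 = 1.0 / (2.0 * compass_sd * compass_sd);
      std::vector<double> w_old(w);
      double Wnew = 0.0;
      for (int i = 0; i < N; ++i) {
        if (w[i] > 0) {
          double d = wrap_pi(th[i] - obs);
          w[i] *= std::exp(-d * d * inv2);
        }
        Wnew += w[i];
      }
      if (Wnew <= 0 || !R_finite(Wnew)) {  // degenerate: fall back to prior
        w = w_old;
        ++n_compass_degen;
      } else {
        reweighted = true;
      }
    }

    double W = 0.0;
    for (int i = 0; i < N; ++i) W += w[i];
    if (W <= 0) {
      // total cull: reinitialize from the disoriented prior over the map
      ++n_reinit;
      for (int i = 0; i < N; ++i) {
        int j = (int)(unif_rand() * M); if (j >= M) j = M - 1;
        x[i] = reinit_pool(j, 0); y[i] = reinit_pool(j, 1);
        th[i] = unif_rand() * 2.0 * M_PI;
        anc[i] = NA_INTEGER;
        w[i] = 1.0;
      }
    } else if (any_dead || reweighted) {
      systematic_resample(x, y, th, anc, w, W);
      std::fill(w.begin(), w.end(), 1.0);
    }

    if (rec_i < nrec && rec_steps[rec_i] == s) {
      double sc = 0, ss = 0, sx = 0, sy = 0;
      for (int i = 0; i < N; ++i) {
        sc += std::cos(th[i]); ss += std::sin(th[i]);
        sx += x[i]; sy += y[i];
      }
      hc[rec_i] = sc / N; hs[rec_i] = ss / N;
      mx[rec_i] = sx / N; my[rec_i] = sy / N;
      if (has_truth) {
        int trow = reverse ? (T - s) : s;
        double tx = truth(trow, 0), ty = truth(trow, 1), sd = 0;
        for (int i = 0; i < N; ++i) {
          double dx = x[i] - tx, dy = y[i] - ty;
          sd += std::sqrt(dx * dx + dy * dy);
        }
        dpost[rec_i] = sd / N;
      }
      if (record_lineage)
        for (int i = 0; i < N; ++i) lineage(rec_i, i) = anc[i];
      ++rec_i;
    }
  }

  NumericMatrix pose(N, 3);
  IntegerVector anc_out(N);
  for (int i = 0; i < N; ++i) {
    pose(i, 0) = x[i]; pose(i, 1) = y[i]; pose(i, 2) = th[i];
    anc_out[i] = anc[i];
  }
  IntegerVector rec_out(nrec);
  for (int i = 0; i < nrec; ++i) rec_out[i] = rec_steps[i];
  return List::create(_["pose"] = pose, _["anc"] = anc_out,
                      _["rec_steps"] = rec_out, _["dpost"] = dpost,
                      _["head_c"] = hc, _["head_s"] = hs,
                      _["mean_x"] = mx, _["mean_y"] = my,
                      _["n_reinit"] = n_reinit,
                      _["n_compass_degenerate"] = n_compass_degen,
                      _["lineage"] = lineage);
}
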