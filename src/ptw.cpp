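// Compiled core: wall-impact geometry, topological neighbour graphs,
// the stimulus/response target, and the Euler-Maruyama time stepper.
// All random draws go through R's RNG so set.seed() governs everything.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// wrap angle to (-pi, pi]
static inline double wrap_pi(double a) {
  const double two_pi = 2.0 * M_PI;
  a -= two_pi * std::floor((a + M_PI) / two_pi);
  if (a > M_PI) a -= two_pi;
  else if (a <= -M_PI) a += two_pi;
  return a;
}

// [[Rcpp::export]]
double cpp_wrap_angle(double a) { return wrap_pi(a); }

// Ray-circle intersection from an interior point.
// Returns (dist_to_impact, signed angle between heading and outward normal).
static inline void wall_impact_one(double px, double py, double th,
                                   double R, double& D, double& thw) {
  double ux = std::cos(th), uy = std::sin(th);
  double pu = px * ux + py * uy;
  double disc = pu * pu + R * R - (px * px + py * py);
  // interior point: disc > 0 always
  double t = -pu + std::sqrt(disc);
  double qx = px + t * ux, qy = py + t * uy;
  double qn = std::sqrt(qx * qx + qy * qy);
  double nx = qx / qn, ny = qy / qn;          // outward normal at impact
  D = t;
  thw = std::atan2(nx * uy - ny * ux, nx * ux + ny * uy);
}

// [[Rcpp::export]]
NumericMatrix cpp_wall_impact(NumericVector px, NumericVector py,
                              NumericVector th, double R) {
  int n = px.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double r2 = px[i] * px[i] + py[i] * py[i];
    if (r2 >= R * R)
      stop("wall_impact: position %d is not strictly inside the tank", i + 1);
    double D, thw;
    wall_impact_one(px[i], py[i], th[i], R, D, thw);
    out(i, 0) = D;
    out(i, 1) = thw;
  }
  return out;
}

// First-shell Voronoi adjacency by the exact bisector half-plane test:
// i and j share a Voronoi edge of positive length iff a segment of their
// perpendicular bisector is closer to {i, j} than to every other point.
// Each third point k contributes one linear inequality along the bisector;
// feasibility of the intersected interval is the adjacency test.
// [[Rcpp::export]]
LogicalMatrix cpp_voronoi_adjacency(NumericVector x, NumericVector y) {
  int n = x.size();
  LogicalMatrix adj(n, n);
  // scale for tolerances
  double xmin = INF, xmax = -INF, ymin = INF, ymax = -INF;
  for (int i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double scale = std::max(xmax - xmin, ymax - ymin);
  if (scale <= 0.0) scale = 1.0;
  double dup2 = 1e-24 * scale * scale;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy < dup2)
        stop("duplicate positions: points %d and %d coincide", i + 1, j + 1);
    }
  double eps_len = 1e-9 * scale;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double dn = std::sqrt(dx * dx + dy * dy);
      double ux = -dy / dn, uy = dx / dn;     // bisector direction
      double lo = -INF, hi = INF;
      bool feas = true;
      for (int k = 0; k < n && feas; ++k) {
        if (k == i || k == j) continue;
        double ex = x[k] - x[i], ey = y[k] - y[i];
        // f(s) = |m+su-pi|^2 - |m+su-pk|^2, written relative to pi to
        // avoid cancellation: 2(m-pi).(pk-pi) - |pk-pi|^2 + 2s u.(pk-pi)
        double c0 = 2.0 * ((mx - x[i]) * ex + (my - y[i]) * ey)
                    - (ex * ex + ey * ey);
        double b = 2.0 * (ux * ex + uy * ey);
        if (std::fabs(b) < 1e-14 * scale) {
          if (c0 > 0.0) feas = false;
        } else if (b > 0.0) {
          double s = -c0 / b;
          if (s < hi) hi = s;
        } else {
          double s = -c0 / b;
          if (s > lo) lo = s;
        }
        if (hi - lo <= eps_len) feas = false;
      }
      if (feas && hi - lo > eps_len) {
        adj(i, j) = true;
        adj(j, i) = true;
      }
    }
  }
  return adj;
}

// Directed K-nearest-neighbour adjacency (row i -> its neighbours).
// [[Rcpp::export]]
LogicalMatrix cpp_knn_adjacency(NumericVector x, NumericVector y, int K) {
  int n = x.size();
  LogicalMatrix adj(n, n);
  int k_use = std::min(K, n - 1);
  std::vector<double> d2(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      d2[j] = (j == i) ? INF : dx * dx + dy * dy;
      idx[j] = j;
    }
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return d2[a] < d2[b]; });
    for (int m = 0; m < k_use; ++m) adj(i, idx[m]) = true;
  }
  return adj;
}

struct ModelP {
  double kw, l, sigma, kp, kv;
  int aw, ap, av;
  int wall_mode;        // 0 = time_to_impact, 1 = distance
  double attract_sat;   // Inf = linear attraction
  double wall_range;    // screening scale: seconds (time mode) or metres
};

static inline double sat_dist(double d, double dsat) {
  if (!std::isfinite(dsat)) return d;
  return dsat * std::tanh(d / dsat);
}

// distance from the fish to the wall, recovered from the impact
// distance and incidence angle (law of cosines in the
// centre-fish-impact triangle)
static inline double dist_to_wall(double D, double thw, double R) {
  double r2 = R * R + D * D - 2.0 * R * D * std::cos(thw);
  double r = std::sqrt(std::max(r2, 0.0));
  return std::max(R - r, 0.0);
}

// Wall component of the target turning speed. Consumes one uniform draw
// only in the measure-zero head-on case thw == 0.
static inline double wall_component(double D, double thw, double v,
                                    double R, const ModelP& p) {
  double s = (thw > 0.0) ? 1.0 : (thw < 0.0 ? -1.0 : 0.0);
  if (s == 0.0) s = (unif_rand() < 0.5) ? -1.0 : 1.0;
  double g = std::cos(thw) * s;
  double screen = std::exp(-dist_to_wall(D, thw, R) / p.wall_range);
  if (p.wall_mode == 0) {
    double T = D / v;
    return p.kw * g * screen / T;
  }
  double vfac = (p.aw == 1) ? v : 1.0;
  return p.kw * vfac * g * screen / D;
}

// Social components for fish i given adjacency row; returns attraction
// and alignment (each already normalised by the neighbour count).
static inline void social_components(int i, const NumericVector& x,
                                     const NumericVector& y,
                                     const NumericVector& th,
                                     const LogicalMatrix& adj, double v,
                                     const ModelP& p, double& att,
                                     double& ali) {
  int n = x.size();
  double sp = 0.0, sv = 0.0;
  int ni = 0;
  for (int j = 0; j < n; ++j) {
    if (j == i || !adj(i, j)) continue;
    ++ni;
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double d = std::sqrt(dx * dx + dy * dy);
    double psi = (d > 0.0) ? wrap_pi(std::atan2(dy, dx) - th[i]) : 0.0;
    double phi = wrap_pi(th[j] - th[i]);
    sp += sat_dist(d, p.attract_sat) * std::sin(psi);
    sv += std::sin(phi);
  }
  if (ni == 0) { att = 0.0; ali = 0.0; return; }
  double vp = (p.ap == 1) ? v : 1.0;
  double vv = (p.av == 1) ? v : 1.0;
  att = p.kp * vp * sp / ni;
  ali = p.kv * vv * sv / ni;
}

static LogicalMatrix make_adjacency(const NumericVector& x,
                                    const NumericVector& y, int method,
                                    int K) {
  int n = x.size();
  if (method == 1) return cpp_voronoi_adjacency(x, y);
  if (method == 2) return cpp_knn_adjacency(x, y, K);
  LogicalMatrix adj(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) adj(i, j) = (i != j);
  return adj;
}

static ModelP unpack_params(List params) {
  ModelP p;
  p.kw = as<double>(params["wall_strength"]);
  p.l = as<double>(params["persistence_length"]);
  p.sigma = as<double>(params["noise_scale"]);
  p.kp = as<double>(params["attract_coeff"]);
  p.kv = as<double>(params["align_coeff"]);
  IntegerVector ex = params["speed_exponents"];
  p.aw = ex[0]; p.ap = ex[1]; p.av = ex[2];
  std::string wm = as<std::string>(params["wall_mode"]);
  p.wall_mode = (wm == "distance") ? 1 : 0;
  p.attract_sat = as<double>(params["attract_sat"]);
  p.wall_range = as<double>(params["wall_range"]);
  return p;
}

// Target turning speeds (wall, attraction, alignment) for every fish at
// one instant. Exposed for diagnostics and for consistency testing
// against the plain-R implementation.
// [[Rcpp::export]]
NumericMatrix cpp_targets(NumericVector x, NumericVector y, NumericVector th,
                          NumericVector v, List params, double R,
                          bool bounded, int method, int K) {
  int n = x.size();
  ModelP p = unpack_params(params);
  LogicalMatrix adj = (n > 1) ? make_adjacency(x, y, method, K)
                              : LogicalMatrix(n, n);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double w = 0.0;
    if (bounded) {
      double D, thw;
      wall_impact_one(x[i], y[i], th[i], R, D, thw);
      w = wall_component(D, thw, v[i], R, p);
    }
    double att = 0.0, ali = 0.0;
    if (n > 1) social_components(i, x, y, th, adj, v[i], p, att, ali);
    out(i, 0) = w; out(i, 1) = att; out(i, 2) = ali;
  }
  return out;
}

// Full Euler-Maruyama integration.
//   speeds: per-fish constant speed; sched (optional, length n_steps):
//   common speed applied to all fish at each step (overrides speeds).
// Saves every save_every-th step after n_transient steps, including the
// state at the start of the saved window (frame 0).
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector y0, NumericVector th0,
                  NumericVector om0, NumericVector speeds,
                  NumericVector sched, List params, double R, bool bounded,
                  int method, int K, double dt, int n_transient,
                  int n_frames, int save_every) {
  int n = x0.size();
  ModelP p = unpack_params(params);
  NumericVector x = clone(x0), y = clone(y0), th = clone(th0), om = clone(om0);
  NumericVector v(n);
  for (int i = 0; i < n; ++i) v[i] = speeds[i];
  bool has_sched = sched.size() > 0;
  int n_steps = n_transient + (n_frames - 1) * save_every;
  if (has_sched && sched.size() < n_steps)
    stop("speed schedule shorter than the number of steps (%d < %d)",
         (int)sched.size(), n_steps);
  NumericMatrix X(n_frames, n), Y(n_frames, n), TH(n_frames, n),
      OM(n_frames, n);
  std::vector<double> omst(n);
  double sq = std::sqrt(dt);
  int n_proj = 0;
  int frame = 0;
  auto save_frame = [&](int f) {
    for (int i = 0; i < n; ++i) {
      X(f, i) = x[i]; Y(f, i) = y[i]; TH(f, i) = th[i]; OM(f, i) = om[i];
    }
  };
  for (int step = 0; step < n_steps; ++step) {
    if (step == n_transient) save_frame(frame++);
    if (has_sched)
      for (int i = 0; i < n; ++i) v[i] = sched[step];
    LogicalMatrix adj = (n > 1) ? make_adjacency(x, y, method, K)
                                : LogicalMatrix(n, n);
    // targets from the current (pre-update) state, fixed fish order
    for (int i = 0; i < n; ++i) {
      double w = 0.0;
      if (bounded) {
        double rr = x[i] * x[i] + y[i] * y[i];
        if (rr >= R * R)
          stop("fish %d left the tank despite projection", i + 1);
        double D, thw;
        wall_impact_one(x[i], y[i], th[i], R, D, thw);
        w = wall_component(D, thw, v[i], R, p);
      }
      double att = 0.0, ali = 0.0;
      if (n > 1) social_components(i, x, y, th, adj, v[i], p, att, ali);
      omst[i] = w + att + ali;
    }
    // synchronous update, one noise draw per fish in fish order
    for (int i = 0; i < n; ++i) {
      double tau = p.l / v[i];
      om[i] += (dt / tau) * (omst[i] - om[i]) + p.sigma * sq * norm_rand();
      if (!std::isfinite(om[i]))
        stop("non-finite angular velocity for fish %d", i + 1);
      th[i] = wrap_pi(th[i] + om[i] * dt);
      x[i] += v[i] * std::cos(th[i]) * dt;
      y[i] += v[i] * std::sin(th[i]) * dt;
      if (bounded) {
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i]);
        if (r >= R) {
          double f = (1.0 - 1e-6) * R / r;
          x[i] *= f; y[i] *= f;
          ++n_proj;
        }
      }
    }
    int k = step + 1 - n_transient;
    if (k > 0 && k % save_every == 0 && frame < n_frames) save_frame(frame++);
  }
  if (frame == 0) save_frame(frame++);  // n_steps == n_transient edge case
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH, _["omega"] = OM,
                      _["n_proj"] = n_proj);
}

// Stimulus regressors for the Ito-discretised regression, evaluated at
// every frame from reconstructed states. S_w = g(theta_w) / (D/vbar) (or
// the distance form), S_p and S_v the neighbour-normalised attraction and
// alignment sums including the configured speed scalings, so that the
// target is kw*S_w + kp*S_p + kv*S_v with unit coefficients on the S's.
// Head-on wall rows get S_w = 0 (measure zero; no RNG in inference).
// [[Rcpp::export]]
List cpp_stimulus_series(NumericMatrix x, NumericMatrix y, NumericMatrix th,
                         NumericVector vbar, List params, double R,
                         bool bounded, int method, int K) {
  int F = x.nrow(), n = x.ncol();
  ModelP p = unpack_params(params);
  NumericMatrix SW(F, n), SP(F, n), SV(F, n);
  NumericVector xs(n), ys(n), ths(n);
  for (int f = 0; f < F; ++f) {
    for (int i = 0; i < n; ++i) {
      xs[i] = x(f, i); ys[i] = y(f, i); ths[i] = th(f, i);
    }
    LogicalMatrix adj = (n > 1) ? make_adjacency(xs, ys, method, K)
                                : LogicalMatrix(n, n);
    for (int i = 0; i < n; ++i) {
      double sw = 0.0;
      if (bounded) {
        double r2 = xs[i] * xs[i] + ys[i] * ys[i];
        if (r2 < R * R) {
          double D, thw;
          wall_impact_one(xs[i], ys[i], ths[i], R, D, thw);
          double s = (thw > 0.0) ? 1.0 : (thw < 0.0 ? -1.0 : 0.0);
          double g = std::cos(thw) * s;
          double screen = std::exp(-dist_to_wall(D, thw, R) / p.wall_range);
          double T = D / vbar[i];
          if (p.wall_mode == 0) sw = g * screen / T;
          else sw = ((p.aw == 1) ? vbar[i] : 1.0) * g * screen / D;
        }
      }
      double sp = 0.0, sv = 0.0;
      if (n > 1) {
        int ni = 0;
        for (int j = 0; j < n; ++j) {
          if (j == i || !adj(i, j)) continue;
          ++ni;
          double dx = xs[j] - xs[i], dy = ys[j] - ys[i];
          double d = std::sqrt(dx * dx + dy * dy);
          double psi = (d > 0.0) ? wrap_pi(std::atan2(dy, dx) - ths[i]) : 0.0;
          double phi = wrap_pi(ths[j] - ths[i]);
          sp += sat_dist(d, p.attract_sat) * std::sin(psi);
          sv += std::sin(phi);
        }
        if (ni > 0) {
          sp /= ni; sv /= ni;
          if (p.ap == 1) sp *= vbar[i];
          if (p.av == 1) sv *= vbar[i];
        }
      }
      SW(f, i) = sw; SP(f, i) = sp; SV(f, i) = sv;
    }
  }
  return List::create(_["S_w"] = SW, _["S_p"] = SP, _["S_v"] = SV);
}
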