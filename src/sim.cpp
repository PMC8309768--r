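#include <Rcpp.h>
using namespace Rcpp;

// Correlated random walk of one tank of fish with centroid attraction and
// reflective walls. All randomness (initial state, per-frame step lengths,
// per-frame von Mises heading noise) is drawn in R beforehand, one stream
// per fish, so this kernel is purely deterministic.
//
// Heading update: the new base direction is the vector sum of
// persistence * (unit vector along the current heading) and
// cohesion * min(d / range, 1) * (unit vector toward the current group
// centroid), where d is the fish's distance to the centroid — a capped
// linear spring, so attraction fades as a fish reaches the group and the
// equilibrium spread is set by the noise/cohesion balance. The pre-drawn
// angular noise is added afterwards. Steps crossing a wall are reflected
// (as is the heading component normal to that wall).
//
// init:   n_fish x 2 initial positions (mm)
// steps:  n_steps x n_fish step lengths (mm per frame)
// noise:  n_steps x n_fish angular noise (radians)
// head0:  initial headings (radians)
// Returns an (n_steps + 1) x n_fish x 2 array of positions in mm.
// [[Rcpp::export]]
NumericVector sim_tank_cpp(NumericMatrix init, NumericMatrix steps,
                           NumericMatrix noise, NumericVector head0,
                           double persistence, double cohesion,
                           double cohesion_range,
                           double arena_w, double arena_h) {
  const int n_fish = init.nrow();
  const int n_steps = steps.nrow();
  const int n_frames = n_steps + 1;

  NumericVector out(Dimension(n_frames, n_fish, 2));
  std::vector<double> x(n_fish), y(n_fish), th(n_fish);
  for (int i = 0; i < n_fish; ++i) {
    x[i] = init(i, 0);
    y[i] = init(i, 1);
    th[i] = head0[i];
    out[0 + n_frames * i] = x[i];
    out[0 + n_frames * (n_fish + i)] = y[i];
  }

  for (int t = 0; t < n_steps; ++t) {
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < n_fish; ++i) { cx += x[i]; cy += y[i]; }
    cx /= n_fish; cy /= n_fish;

    for (int i = 0; i < n_fish; ++i) {
      double vx = persistence * std::cos(th[i]);
      double vy = persistence * std::sin(th[i]);
      double bx = cx - x[i], by = cy - y[i];
      double bn = std::sqrt(bx * bx + by * by);
      if (bn > 1e-12 && cohesion > 0.0) {
        double pull = cohesion * std::min(bn / cohesion_range, 1.0);
        vx += pull * bx / bn;
        vy += pull * by / bn;
      }
      double base = (std::sqrt(vx * vx + vy * vy) > 1e-12)
                      ? std::atan2(vy, vx) : th[i];
      double ang = base + noise(t, i);
      double hx = std::cos(ang), hy = std::sin(ang);
      double nx = x[i] + steps(t, i) * hx;
      double ny = y[i] + steps(t, i) * hy;
      // reflective walls; heading reflects with the position
      for (int guard = 0; guard < 64 &&
           (nx < 0 || nx > arena_w || ny < 0 || ny > arena_h); ++guard) {
        if (nx < 0)       { nx = -nx;               hx = -hx; }
        if (nx > arena_w) { nx = 2 * arena_w - nx;  hx = -hx; }
        if (ny < 0)       { ny = -ny;               hy = -hy; }
        if (ny > arena_h) { ny = 2 * arena_h - ny;  hy = -hy; }
      }
      // pathological step lengths could defeat the guard; clamp as last resort
      if (nx < 0) nx = 0; else if (nx > arena_w) nx = arena_w;
      if (ny < 0) ny = 0; else if (ny > arena_h) ny = arena_h;
      x[i] = nx; y[i] = ny;
      th[i] = std::atan2(hy, hx);
      out[(t + 1) + n_frames * i] = nx;
      out[(t + 1) + n_frames * (n_fish + i)] = ny;
    }
  }
  return out;
}
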