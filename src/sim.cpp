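#include <Rcpp.h>
using namespace Rcpp;

// Per-frame sampler for the behavioural state machine.
// States (0-based): 0 rest, 1 straight_walk, 2 circle_ccw, 3 circle_cw,
// 4 wall_follow.  Dwell times are exponential; bout speed and posture are
// drawn at bout onset; heading follows a correlated random walk for walking
// states and a constant angular rate for circling states.  The centre is
// reflected off the walls (margin `refl_margin`); nose and tail are placed
// on the body axis at the configured distances scaled by the bout's
// elongation draw, then jittered and clamped into the arena (a tracker sees
// the nose pressed against the wall, not outside it).
//
// stretch_prob >= 0 switches the posture model to a per-bout Bernoulli
// stretched/bent mixture with elongation means stretch_elong / bent_elong,
// used by the cohort generator to target stretched-posture occupancy.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate_session(int n_frames, double rate,
                          NumericVector dwell, NumericVector speed_mean,
                          NumericVector speed_sd, NumericVector turn_rate,
                          NumericVector heading_sd, NumericVector elong_mean,
                          NumericVector elong_sd, NumericMatrix trans,
                          double arena_w, double arena_h, double refl_margin,
                          double d_nose, double d_tail, double jitter_sd,
                          int init_state, double init_x, double init_y,
                          double stretch_prob, double stretch_elong,
                          double bent_elong) {
  const int S = dwell.size();
  const double dt = 1.0 / rate;
  const double deg2rad = M_PI / 180.0;

  NumericVector t(n_frames), nx(n_frames), ny(n_frames), cx(n_frames),
      cy(n_frames), tx(n_frames), ty(n_frames);
  IntegerVector state_out(n_frames);

  int s = init_state;
  double x = init_x, y = init_y;
  double phi = R::runif(0.0, 2.0 * M_PI);
  double remaining = R::rexp(dwell[s]);
  double speed = std::max(0.0, R::rnorm(speed_mean[s], speed_sd[s]));
  double bout_elong = elong_mean[s];
  if (stretch_prob >= 0.0)
    bout_elong = (R::unif_rand() < stretch_prob) ? stretch_elong : bent_elong;

  const double lo_x = refl_margin, hi_x = arena_w - refl_margin;
  const double lo_y = refl_margin, hi_y = arena_h - refl_margin;

  for (int i = 0; i < n_frames; ++i) {
    // heading update
    if (s == 2) phi += turn_rate[s] * deg2rad * dt;        // ccw
    else if (s == 3) phi -= turn_rate[s] * deg2rad * dt;   // cw
    else if (heading_sd[s] > 0.0) phi += R::rnorm(0.0, heading_sd[s] * deg2rad);

    if (s == 4) {
      // wall_follow: near a wall, steer along the tangent closest to the
      // current heading; otherwise behave like a straight walk
      double dxw = std::min(x - lo_x, hi_x - x);
      double dyw = std::min(y - lo_y, hi_y - y);
      if (std::min(dxw, dyw) < 6.0) {
        double tang = (dxw < dyw) ? M_PI / 2.0 : 0.0;  // along vertical/horiz wall
        double c1 = std::cos(phi - tang), c2 = std::cos(phi - (tang + M_PI));
        phi = (c1 >= c2) ? tang : tang + M_PI;
      }
    }

    // advance and reflect
    x += speed * dt * std::cos(phi);
    y += speed * dt * std::sin(phi);
    if (x < lo_x) { x = 2.0 * lo_x - x; phi = M_PI - phi; }
    else if (x > hi_x) { x = 2.0 * hi_x - x; phi = M_PI - phi; }
    if (y < lo_y) { y = 2.0 * lo_y - y; phi = -phi; }
    else if (y > hi_y) { y = 2.0 * hi_y - y; phi = -phi; }

    double e = bout_elong;
    if (elong_sd[s] > 0.0) e += R::rnorm(0.0, elong_sd[s]);
    if (e < 0.05) e = 0.05;
    if (e > 1.0) e = 1.0;

    double ux = std::cos(phi), uy = std::sin(phi);
    double nxi = x + e * d_nose * ux + R::rnorm(0.0, jitter_sd);
    double nyi = y + e * d_nose * uy + R::rnorm(0.0, jitter_sd);
    double txi = x - e * d_tail * ux + R::rnorm(0.0, jitter_sd);
    double tyi = y - e * d_tail * uy + R::rnorm(0.0, jitter_sd);
    double cxi = x + R::rnorm(0.0, jitter_sd);
    double cyi = y + R::rnorm(0.0, jitter_sd);

    // clamp tracked points into the arena box
    auto clampw = [&](double v, double hi) {
      return v < 0.0 ? 0.0 : (v > hi ? hi : v);
    };
    t[i] = i * dt;
    nx[i] = clampw(nxi, arena_w); ny[i] = clampw(nyi, arena_h);
    cx[i] = clampw(cxi, arena_w); cy[i] = clampw(cyi, arena_h);
    tx[i] = clampw(txi, arena_w); ty[i] = clampw(tyi, arena_h);
    state_out[i] = s;

    remaining -= dt;
    if (remaining <= 0.0) {
      // sample next state from this row of the transition matrix
      double u = R::unif_rand(), cum = 0.0;
      int nxt = S - 1;
      for (int j = 0; j < S; ++j) {
        cum += trans(s, j);
        if (u <= cum) { nxt = j; break; }
      }
      s = nxt;
      remaining = R::rexp(dwell[s]);
      speed = std::max(0.0, R::rnorm(speed_mean[s], speed_sd[s]));
      bout_elong = elong_mean[s];
      if (stretch_prob >= 0.0)
        bout_elong = (R::unif_rand() < stretch_prob) ? stretch_elong : bent_elong;
    }
  }

  return List::create(_["t"] = t, _["nose_x"] = nx, _["nose_y"] = ny,
                      _["centre_x"] = cx, _["centre_y"] = cy,
                      _["tail_x"] = tx, _["tail_y"] = ty,
                      _["state"] = state_out);
}
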