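#include <Rcpp.h>
using namespace Rcpp;

// Gated resampling of the centre path.  A frame is accepted when the centre
// has moved at least `min_step` cm since the last accepted frame ("Minimal
// Distance Moved" gate).  Invalid frames contribute nothing; the first valid
// frame after a run of invalid frames re-anchors the gate and starts a new
// segment, so no displacement is accumulated across an untracked gap.
//
// Returns accepted frame indices (1-based, anchors included), a segment id
// per accepted frame, and the gated total distance in cm.
// [[Rcpp::export]]
List cpp_gated_path(NumericVector x, NumericVector y, LogicalVector valid,
                    double min_step) {
  const int n = x.size();
  std::vector<int> acc_idx;
  std::vector<int> acc_seg;
  double dist = 0.0;
  double ax = 0.0, ay = 0.0;
  bool have_anchor = false;
  bool in_gap = false;
  int seg = 0;

  for (int i = 0; i < n; ++i) {
    if (valid[i] != TRUE) {
      if (have_anchor) in_gap = true;
      continue;
    }
    if (!have_anchor || in_gap) {
      // (re-)anchor without accumulating displacement across the gap
      ax = x[i]; ay = y[i];
      have_anchor = true;
      in_gap = false;
      ++seg;
      acc_idx.push_back(i + 1);
      acc_seg.push_back(seg);
      continue;
    }
    double dx = x[i] - ax, dy = y[i] - ay;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d >= min_step) {
      dist += d;
      ax = x[i]; ay = y[i];
      acc_idx.push_back(i + 1);
      acc_seg.push_back(seg);
    }
  }
  return List::create(_["distance"] = dist,
                      _["accepted"] = wrap(acc_idx),
                      _["segment"] = wrap(acc_seg));
}

static inline double wrap180(double d) {
  // reduce to (-180, 180] without fmod
  d -= 360.0 * std::floor((d + 180.0) / 360.0);
  if (d == -180.0) d = 180.0;
  return d;
}

// Signed 360-degree turn accumulator over a body-axis angle sequence
// (degrees) sampled at the gate-accepted frames.  `segment` marks breaks
// across untracked gaps: the accumulator restarts there.  Whenever the
// running angle retreats more than `tol` degrees from its extreme since the
// last reset/count, the accumulator is zeroed so meandering cannot bank
// partial turns indefinitely.  Returns c(ccw, cw) counts (ccw = positive
// image-frame rotation).
// [[Rcpp::export]]
IntegerVector cpp_count_turns(NumericVector theta, IntegerVector segment,
                              double tol) {
  const int n = theta.size();
  int ccw = 0, cw = 0;
  double acc = 0.0, ext = 0.0;
  for (int k = 1; k < n; ++k) {
    if (segment[k] != segment[k - 1]) {
      acc = 0.0; ext = 0.0;
      continue;
    }
    acc += wrap180(theta[k] - theta[k - 1]);
    while (acc >= 360.0) { ++ccw; acc -= 360.0; ext = acc; }
    while (acc <= -360.0) { ++cw; acc += 360.0; ext = acc; }
    if (std::fabs(acc) > std::fabs(ext)) ext = acc;
    if ((ext > 0.0 && ext - acc > tol) || (ext < 0.0 && acc - ext > tol)) {
      acc = 0.0; ext = 0.0;
    }
  }
  return IntegerVector::create(ccw, cw);
}
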