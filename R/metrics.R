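#' Turn-detection parameters
#'
#' @param min_step Minimal Distance Moved gate in cm (default 1): a frame is
#'   accepted only once the centre has moved at least this far since the
#'   last accepted frame, which suppresses tracking jitter.
#' @param lesion_side Side of the 6-OHDA lesion (study constant `"right"`).
#' @param view Camera viewpoint (see [arena_spec()]); together with
#'   `lesion_side` this fixes which image-frame rotation direction counts as
#'   ipsiversive.
#' @param reset_tol Degrees of opposite-direction accumulation after which
#'   the signed turn accumulator resets to zero (default 45), so a
#'   meandering walk cannot bank partial turns indefinitely.
#' @return An object of class `turn_params`.  The full-turn angle is fixed
#'   at 360 degrees.
#' @export
turn_params <- function(min_step = 1, lesion_side = c("right", "left"),
                        view = c("from-below", "from-above"),
                        reset_tol = 45) {
  lesion_side <- match.arg(lesion_side)
  view <- match.arg(view)
  if (!is.numeric(min_step) || min_step < 0)
    stop("min_step must be a non-negative length (cm)")
  if (!is.numeric(reset_tol) || reset_tol <= 0)
    stop("reset_tol must be a positive angle (deg)")
  structure(list(min_step = min_step, full_turn = 360,
                 lesion_side = lesion_side, view = view,
                 reset_tol = reset_tol),
            class = "turn_params")
}

#' Posture (body-elongation) parameters
#'
#' Elongation is the nose-tail extent normalised by a reference length; the
#' animal is "stretched" (quadrupedal, non-bent trunk) when elongation is at
#' or above `threshold`.
#'
#' @param threshold Elongation threshold (default 0.70).
#' @param reference `"session-percentile"` (default): the reference length
#'   is a high percentile of the session's own nose-tail distances, robust
#'   to outlier frames; or `"fixed-length"` with `fixed_length` in cm for
#'   cross-animal comparability.
#' @param percentile Percentile used by the session reference (default 0.95).
#' @param fixed_length Reference length in cm when `reference =
#'   "fixed-length"`.
#' @param measure `"chord"` (nose-tail straight distance, default) or
#'   `"arc"` (nose-centre plus centre-tail).
#' @return An object of class `posture_params`.
#' @export
posture_params <- function(threshold = 0.70,
                           reference = c("session-percentile", "fixed-length"),
                           percentile = 0.95, fixed_length = NULL,
                           measure = c("chord", "arc")) {
  reference <- match.arg(reference)
  measure <- match.arg(measure)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 1)
    stop("percentile must lie in (0, 1]")
  if (reference == "fixed-length" &&
      (is.null(fixed_length) || !is.numeric(fixed_length) || fixed_length <= 0))
    stop("fixed-length reference requires a positive fixed_length (cm)")
  structure(list(threshold = threshold, reference = reference,
                 percentile = percentile, fixed_length = fixed_length,
                 measure = measure),
            class = "posture_params")
}

#' Space-occupancy (gyration radius) parameters
#'
#' @param bin Bin width in seconds (default 10).
#' @param observation Observation window in seconds over which bin radii are
#'   averaged; `NA` (default) uses every complete bin in the session, the
#'   study protocol corresponds to 3300.
#' @param min_valid_frac Minimum fraction of valid samples for a bin to be
#'   used (default 0.8); sparser bins are excluded rather than renormalised.
#' @return An object of class `gyration_params`.
#' @export
gyration_params <- function(bin = 10, observation = NA, min_valid_frac = 0.8) {
  if (!is.numeric(bin) || bin <= 0) stop("bin must be positive (s)")
  if (!is.na(observation) && (!is.numeric(observation) || observation <= 0 ||
                              observation %% bin != 0))
    stop("observation must be a positive multiple of the bin width")
  if (!is.numeric(min_valid_frac) || min_valid_frac <= 0 || min_valid_frac > 1)
    stop("min_valid_frac must lie in (0, 1]")
  structure(list(bin = bin, observation = observation,
                 min_valid_frac = min_valid_frac),
            class = "gyration_params")
}

#' Total distance travelled
#'
#' Sums centre-point displacements over gate-accepted steps: a step is
#' accepted when the centre has moved at least `min_step` cm since the last
#' accepted sample, so stationary tracking jitter accumulates no distance.
#' Invalid frames contribute nothing, and no displacement is accumulated
#' across an untracked gap.
#'
#' @param traj A [trajectory()] passing QC.
#' @param min_step Gate in cm (default 1, the turn detector's Minimal
#'   Distance Moved).
#' @param qc_limit Maximum tolerated invalid-frame fraction (default 0.1).
#' @return Distance in cm.
#' @export
compute_distance <- function(traj, min_step = 1, qc_limit = 0.1) {
  assert_scoreable(traj, qc_limit)
  fr <- traj$frames
  cpp_gated_path(fr$centre_x, fr$centre_y, fr$valid, min_step)$distance
}

#' Count ipsiversive and contraversive 360-degree turns
#'
#' The body-axis angle (direction of the nose relative to the centre) is
#' sampled at gate-accepted frames, unwrapped, and fed to a signed
#' accumulator; each time the accumulator reaches +/-360 degrees one full
#' turn of that sign is counted and 360 degrees subtracted.  The
#' accumulator resets to zero after more than `reset_tol` degrees of
#' opposite-direction accumulation.  For a right-side lesion viewed from
#' below, counter-clockwise image rotation is ipsiversive and clockwise
#' contraversive; flipping either `lesion_side` or `view` swaps the labels.
#'
#' @param traj A [trajectory()] passing QC.
#' @param params A [turn_params()].
#' @param qc_limit Maximum tolerated invalid-frame fraction.
#' @return Named integer vector `c(ipsi = ..., contra = ...)`.
#' @export
count_turns <- function(traj, params = turn_params(), qc_limit = 0.1) {
  assert_scoreable(traj, qc_limit)
  stopifnot(inherits(params, "turn_params"))
  fr <- traj$frames
  gate <- cpp_gated_path(fr$centre_x, fr$centre_y, fr$valid, params$min_step)
  idx <- gate$accepted
  seg <- gate$segment
  dx <- fr$nose_x[idx] - fr$centre_x[idx]
  dy <- fr$nose_y[idx] - fr$centre_y[idx]
  defined <- sqrt(dx^2 + dy^2) > 1e-9   # nose coincident with centre: skip
  theta <- atan2(dy[defined], dx[defined]) * 180 / pi
  counts <- cpp_count_turns(theta, seg[defined], params$reset_tol)
  ccw <- counts[1]; cw <- counts[2]
  flips <- (params$lesion_side == "left") + (params$view == "from-above")
  if (flips %% 2 == 0) c(ipsi = ccw, contra = cw) else c(ipsi = cw, contra = ccw)
}

# Nose-tail extent per frame, per the configured measure.
body_extent <- function(fr, measure) {
  if (measure == "chord") {
    sqrt((fr$nose_x - fr$tail_x)^2 + (fr$nose_y - fr$tail_y)^2)
  } else {
    sqrt((fr$nose_x - fr$centre_x)^2 + (fr$nose_y - fr$centre_y)^2) +
      sqrt((fr$centre_x - fr$tail_x)^2 + (fr$centre_y - fr$tail_y)^2)
  }
}

#' Time spent in a stretched (non-bent) posture
#'
#' Per-frame elongation is the nose-tail extent divided by the reference
#' length and clipped to `[0, 1]`; the returned value is the total time
#' (valid frames times the frame period) with elongation at or above the
#' threshold.
#'
#' @param traj A [trajectory()] passing QC.
#' @param params A [posture_params()].
#' @param qc_limit Maximum tolerated invalid-frame fraction.
#' @return Stretched time in seconds.
#' @export
stretched_time <- function(traj, params = posture_params(), qc_limit = 0.1) {
  assert_scoreable(traj, qc_limit)
  stopifnot(inherits(params, "posture_params"))
  fr <- traj$frames[traj$frames$valid, ]
  d <- body_extent(fr, params$measure)
  ref <- if (params$reference == "fixed-length") params$fixed_length
         else quantile(d, params$percentile, names = FALSE)
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate elongation reference length (<= 0)")
  e <- pmin(pmax(d / ref, 0), 1)
  sum(e >= params$threshold) / traj$rate
}

#' Space occupancy as the mean gyration radius
#'
#' The session is cut into fixed bins (10 s, i.e. 250 samples at 25 Hz).
#' Within each bin the centroid of the valid centre positions is taken and
#' the bin radius is the mean distance of those positions from the
#' centroid; the metric is the mean bin radius over the observation window.
#' Bins with fewer than `min_valid_frac` valid samples are excluded (their
#' indices are attached as attribute `excluded_bins`).
#'
#' @param traj A [trajectory()] passing QC.
#' @param params A [gyration_params()].
#' @param qc_limit Maximum tolerated invalid-frame fraction.
#' @return Mean gyration radius in cm.
#' @export
gyration_radius <- function(traj, params = gyration_params(), qc_limit = 0.1) {
  assert_scoreable(traj, qc_limit)
  stopifnot(inherits(params, "gyration_params"))
  fr <- traj$frames
  per_bin <- round(params$bin * traj$rate)
  if (per_bin < 2) stop("bin too short for the sampling rate")
  nbin_avail <- nrow(fr) %/% per_bin
  nbin <- if (is.na(params$observation)) nbin_avail
          else round(params$observation / params$bin)
  if (nbin > nbin_avail)
    stop("session does not cover the observation window")
  if (nbin < 1) stop("no complete gyration bin in the session")

  r_bin <- rep(NA_real_, nbin)
  for (b in seq_len(nbin)) {
    i <- ((b - 1) * per_bin + 1):(b * per_bin)
    ok <- fr$valid[i]
    if (mean(ok) < params$min_valid_frac) next
    x <- fr$centre_x[i][ok]; y <- fr$centre_y[i][ok]
    r_bin[b] <- mean(sqrt((x - mean(x))^2 + (y - mean(y))^2))
  }
  usable <- which(!is.na(r_bin))
  if (length(usable) == 0L) stop("no usable gyration bins (all below the valid-sample fraction)")
  structure(mean(r_bin[usable]), excluded_bins = setdiff(seq_len(nbin), usable))
}

#' Score all five behavioural metrics for one session
#'
#' Assembles distance travelled, ipsi-/contraversive turn counts, stretched
#' time and space occupancy with a shared QC gate.  Deterministic for fixed
#' inputs.
#'
#' @param traj A [trajectory()].
#' @param turn,posture,gyr Parameter sets ([turn_params()],
#'   [posture_params()], [gyration_params()]).
#' @param qc_limit Maximum tolerated invalid-frame fraction (default 0.1).
#' @return A one-row data frame of class `behaviour_summary` with columns
#'   `animal_id`, `distance_cm`, `ipsi_turns`, `contra_turns`,
#'   `stretched_time_s`, `space_occupancy_cm`, `qc_invalid_fraction`.
#' @export
score_animal <- function(traj, turn = turn_params(),
                         posture = posture_params(),
                         gyr = gyration_params(observation = NA),
                         qc_limit = 0.1) {
  assert_scoreable(traj, qc_limit)
  wrap <- function(metric, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("metric '%s' failed for '%s': %s",
                   metric, traj$animal_id, conditionMessage(e)), call. = FALSE))
  }
  dist <- wrap("distance", compute_distance(traj, turn$min_step, qc_limit))
  turns <- wrap("turns", count_turns(traj, turn, qc_limit))
  stretch <- wrap("stretched_time", stretched_time(traj, posture, qc_limit))
  gyrad <- wrap("space_occupancy",
                as.numeric(gyration_radius(traj, gyr, qc_limit)))
  structure(data.frame(animal_id = traj$animal_id,
                       distance_cm = dist,
                       ipsi_turns = unname(turns["ipsi"]),
                       contra_turns = unname(turns["contra"]),
                       stretched_time_s = stretch,
                       space_occupancy_cm = gyrad,
                       qc_invalid_fraction = traj$invalid_fraction),
            class = c("behaviour_summary", "data.frame"))
}
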