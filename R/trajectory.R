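#' Open-field arena geometry
#'
#' Describes the rectangular open field and the coordinate conventions of the
#' tracking export.  The canonical frame has its origin at the bottom-left
#' corner, x rightward and y upward, in cm, as seen by a below-floor camera.
#' The `view` matters only for mapping image-frame rotation direction onto
#' ipsi-/contraversive turn labels (see [count_turns()]): a from-above camera
#' mirrors handedness.
#'
#' @param width,height Arena side lengths in cm (default 50 x 40).
#' @param origin Corner carrying the coordinate origin.
#' @param view Camera viewpoint, `"from-below"` (default) or `"from-above"`.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()
#' @export
arena_spec <- function(width = 50, height = 40,
                       origin = c("bottom-left", "top-left"),
                       view = c("from-below", "from-above")) {
  origin <- match.arg(origin)
  view <- match.arg(view)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("arena width must be a positive number (cm)")
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0)
    stop("arena height must be a positive number (cm)")
  structure(list(width = width, height = height,
                 origin = origin, view = view),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm, origin %s, viewed %s\n",
              x$width, x$height, x$origin, x$view))
  invisible(x)
}

#' Construct a three-point trajectory
#'
#' A trajectory is one animal's open-field session: per-frame nose, centre
#' and tail coordinates (cm) at a fixed sampling rate, with per-frame
#' validity and interpolation flags.  Frames are valid only when all three
#' points were tracked and lie inside the arena bounding box (plus a small
#' overshoot margin); downstream metrics accumulate nothing over invalid
#' frames.
#'
#' @param frames A data frame with columns `t`, `nose_x`, `nose_y`,
#'   `centre_x`, `centre_y`, `tail_x`, `tail_y` and optionally `valid` and
#'   `interpolated` (both default `TRUE`/`FALSE`).
#' @param rate Sampling rate in Hz (default 25).
#' @param animal_id Identifier for the animal/session.
#' @param arena An [arena_spec()].
#' @param margin Overshoot margin (cm) allowed outside the arena box before
#'   a frame is declared invalid.
#' @return An object of class `trajectory`: the frame table plus `rate`,
#'   `duration` (time span, s), `animal_id`, `arena` and the invalid-frame
#'   fraction.
#' @seealso [read_trajectory()], [simulate_session()]
#' @export
trajectory <- function(frames, rate = 25, animal_id = "animal",
                       arena = arena_spec(), margin = 0.5) {
  need <- c("t", "nose_x", "nose_y", "centre_x", "centre_y", "tail_x", "tail_y")
  if (!all(need %in% names(frames)))
    stop("frames must contain columns: ", paste(need, collapse = ", "))
  frames <- as.data.frame(frames)
  n <- nrow(frames)
  if (n == 0L) stop("trajectory has no frames")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive (Hz)")
  if (any(diff(frames$t) <= 0)) stop("timestamps must be strictly increasing")
  if (frames$t[1] < 0) stop("timestamps must be non-negative")

  coords <- frames[, need[-1]]
  finite_ok <- rowSums(!is.finite(as.matrix(coords))) == 0L
  inbox <- finite_ok
  xs <- c("nose_x", "centre_x", "tail_x"); ys <- c("nose_y", "centre_y", "tail_y")
  inbox[finite_ok] <-
    rowSums(coords[finite_ok, xs, drop = FALSE] < -margin |
            coords[finite_ok, xs, drop = FALSE] > arena$width + margin) == 0L &
    rowSums(coords[finite_ok, ys, drop = FALSE] < -margin |
            coords[finite_ok, ys, drop = FALSE] > arena$height + margin) == 0L
  if (is.null(frames$valid)) frames$valid <- TRUE
  frames$valid <- frames$valid & inbox
  if (is.null(frames$interpolated)) frames$interpolated <- FALSE

  structure(list(frames = frames, rate = rate,
                 duration = frames$t[n] - frames$t[1],
                 animal_id = as.character(animal_id), arena = arena,
                 invalid_fraction = mean(!frames$valid)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s: %d frames @ %g Hz (%.1f s), %.1f%% invalid\n",
    x$animal_id, nrow(x$frames), x$rate, x$duration,
    100 * x$invalid_fraction))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$frames)

# Refuse to score a session whose untracked fraction exceeds the QC ceiling.
assert_scoreable <- function(traj, qc_limit = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$invalid_fraction >= qc_limit)
    stop(sprintf(
      "QC failure for '%s': %.1f%% of frames invalid (limit %.1f%%)",
      traj$animal_id, 100 * traj$invalid_fraction, 100 * qc_limit))
  invisible(traj)
}
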