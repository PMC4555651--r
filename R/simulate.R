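SIM_STATES <- c("rest", "straight_walk", "circle_ccw", "circle_cw",
                "wall_follow")

#' Phenotype configuration for the locomotion simulator
#'
#' Behaviour is modelled as a continuous-time Markov state machine over five
#' states (rest, straight walk, counter-clockwise circling, clockwise
#' circling, wall following) with exponential dwell times.  The centre point
#' follows the active state's kinematics (correlated random walk for
#' walking, constant-radius arc for circling) inside the arena; nose and
#' tail are placed along the body axis at the configured distances scaled by
#' the state's elongation draw, plus isotropic tracking jitter.
#'
#' The built-in labels parameterise the main treatment phenotypes of the
#' hemiparkinsonian open-field assay: `vehicle` (hypokinetic, mostly rest),
#' `mono_like` (single-drug: moderate activity, mild contraversive
#' turning), `combo_like` (A2A/NR2B combination-like: high-speed straight
#' exploration, stretched posture, balanced turning), `ldopa_ben_like`
#' (full dopaminergic stimulation: tight stereotyped contraversive circling
#' with bent trunk) and `ldopa25_like` (weak dopaminergic stimulation:
#' mixed circling and walking with straighter trunk).  Directions assume a
#' right-side lesion viewed from below, where contraversive = clockwise.
#'
#' @param label One of the phenotype labels above.
#' @param ... Named overrides for any default field: `dwell`, `next_prob`,
#'   `circling_bias` (probability that a circling bout is
#'   counter-clockwise), `turn_rate` (deg/s), `circle_radius` (cm),
#'   `speed_mean`, `speed_sd`, `heading_sd` (deg/step), `elong_mean`,
#'   `elong_sd`, `body` (`c(nose=, tail=)` cm), `jitter_sd` (cm), `seed`.
#' @return An object of class `phenotype_config`.
#' @export
phenotype_config <- function(label = c("vehicle", "mono_like", "combo_like",
                                       "ldopa_ben_like", "ldopa25_like"),
                             ...) {
  label <- match.arg(label)
  cfg <- switch(label,
    vehicle = list(
      dwell = c(20, 4, 3, 3, 6),
      next_prob = c(rest = 0.60, walk = 0.20, circle = 0.06, wall = 0.14),
      circling_bias = 0.5, turn_rate = 30, circle_radius = 6,
      speed_mean = c(0, 4, NA, NA, 5), speed_sd = c(0, 0.8, 0.3, 0.3, 0.8),
      heading_sd = c(2, 4, 0, 0, 2),
      elong_mean = c(0.55, 0.75, 0.60, 0.60, 0.75)),
    mono_like = list(
      dwell = c(5, 8, 6, 6, 8),
      next_prob = c(rest = 0.30, walk = 0.35, circle = 0.15, wall = 0.20),
      circling_bias = 0.45, turn_rate = 45, circle_radius = 6,
      speed_mean = c(0, 9, NA, NA, 7), speed_sd = c(0, 1.2, 0.3, 0.3, 1),
      heading_sd = c(2, 4, 0, 0, 2),
      elong_mean = c(0.60, 0.80, 0.65, 0.65, 0.80)),
    combo_like = list(
      dwell = c(2, 15, 4, 4, 12),
      next_prob = c(rest = 0.15, walk = 0.50, circle = 0.10, wall = 0.25),
      circling_bias = 0.5, turn_rate = 45, circle_radius = 6,
      speed_mean = c(0, 14, NA, NA, 10), speed_sd = c(0, 2, 0.3, 0.3, 1.5),
      heading_sd = c(2, 4, 0, 0, 2),
      elong_mean = c(0.70, 0.88, 0.70, 0.70, 0.88)),
    ldopa_ben_like = list(
      dwell = c(2, 2, 30, 30, 2),
      next_prob = c(rest = 0.10, walk = 0.10, circle = 0.76, wall = 0.04),
      circling_bias = 0.05, turn_rate = 60, circle_radius = 4.5,
      speed_mean = c(0, 8, NA, NA, 6), speed_sd = c(0, 1, 0.3, 0.3, 1),
      heading_sd = c(2, 4, 0, 0, 2),
      elong_mean = c(0.60, 0.80, 0.45, 0.45, 0.70)),
    ldopa25_like = list(
      dwell = c(4, 6, 12, 12, 6),
      next_prob = c(rest = 0.20, walk = 0.30, circle = 0.30, wall = 0.20),
      circling_bias = 0.20, turn_rate = 50, circle_radius = 5.5,
      speed_mean = c(0, 10, NA, NA, 8), speed_sd = c(0, 1.2, 0.3, 0.3, 1),
      heading_sd = c(2, 4, 0, 0, 2),
      elong_mean = c(0.60, 0.80, 0.70, 0.70, 0.80)))
  cfg$label <- label
  cfg$elong_sd <- rep(0.04, 5)
  cfg$body <- c(nose = 9, tail = 11)
  cfg$jitter_sd <- 0.15
  cfg$seed <- NULL
  cfg$stretch_prob <- -1   # < 0: posture driven by per-state elongation
  cfg$stretch_elong <- 0.9
  cfg$bent_elong <- 0.5

  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "trans"))
  if (length(unknown)) stop("unknown phenotype fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots

  # circling speed follows from radius and angular rate unless overridden
  circ_speed <- cfg$circle_radius * cfg$turn_rate * pi / 180
  cfg$speed_mean[3:4][is.na(cfg$speed_mean[3:4])] <- circ_speed

  if (is.null(dots$trans)) {
    q <- cfg$next_prob / sum(cfg$next_prob)
    row <- c(q["rest"], q["walk"],
             q["circle"] * cfg$circling_bias,
             q["circle"] * (1 - cfg$circling_bias), q["wall"])
    cfg$trans <- matrix(rep(unname(row), 5), nrow = 5, byrow = TRUE,
                        dimnames = list(SIM_STATES, SIM_STATES))
  } else cfg$trans <- dots$trans

  validate_phenotype(cfg)
}

validate_phenotype <- function(cfg) {
  stopifnot(length(cfg$dwell) == 5, length(cfg$speed_mean) == 5,
            length(cfg$elong_mean) == 5)
  if (any(cfg$dwell <= 0)) stop("dwell times must be positive")
  if (any(cfg$speed_mean < 0)) stop("speeds must be non-negative")
  if (cfg$circling_bias < 0 || cfg$circling_bias > 1)
    stop("circling_bias must lie in [0, 1]")
  if (any(cfg$elong_mean <= 0 | cfg$elong_mean > 1))
    stop("elongation means must lie in (0, 1]")
  if (any(abs(rowSums(cfg$trans) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  structure(cfg, class = "phenotype_config")
}

#' Simulate one open-field session
#'
#' Samples a state-machine path for a [phenotype_config()] and returns the
#' three-point [trajectory()].  Kinematics that would exit the arena are
#' reflected at the walls; tracked points are clamped into the arena box
#' (the tracker sees a nose pressed against the wall, not beyond it).
#' Fully reproducible from the seed.
#'
#' @param cfg A [phenotype_config()].
#' @param duration Session length in seconds (default 3300, i.e. 55 min).
#' @param rate Sampling rate in Hz (default 25).
#' @param seed Integer seed (default `cfg$seed`); `NULL` uses the current
#'   RNG stream.
#' @param arena An [arena_spec()].
#' @param animal_id Identifier stored in the trajectory.
#' @return A [trajectory()] with the per-frame behavioural state attached as
#'   attribute `states` (factor over the five state names).
#' @export
simulate_session <- function(cfg, duration = 3300, rate = 25,
                             seed = cfg$seed, arena = arena_spec(),
                             animal_id = cfg$label) {
  stopifnot(inherits(cfg, "phenotype_config"))
  n <- round(duration * rate)
  if (n < 2) stop("duration too short for the sampling rate")
  sim <- with_seed(seed, {
    init_state <- sample.int(5, 1, prob = cfg$trans[1, ])
    cpp_simulate_session(
      n_frames = n, rate = rate,
      dwell = cfg$dwell, speed_mean = cfg$speed_mean,
      speed_sd = cfg$speed_sd,
      turn_rate = rep(cfg$turn_rate, 5), heading_sd = cfg$heading_sd,
      elong_mean = cfg$elong_mean, elong_sd = cfg$elong_sd,
      trans = cfg$trans,
      arena_w = arena$width, arena_h = arena$height, refl_margin = 2,
      d_nose = cfg$body[["nose"]], d_tail = cfg$body[["tail"]],
      jitter_sd = cfg$jitter_sd,
      init_state = init_state - 1L,
      init_x = arena$width / 2, init_y = arena$height / 2,
      stretch_prob = cfg$stretch_prob,
      stretch_elong = cfg$stretch_elong, bent_elong = cfg$bent_elong)
  })
  fr <- data.frame(t = sim$t, nose_x = sim$nose_x, nose_y = sim$nose_y,
                   centre_x = sim$centre_x, centre_y = sim$centre_y,
                   tail_x = sim$tail_x, tail_y = sim$tail_y)
  traj <- trajectory(fr, rate = rate, animal_id = animal_id, arena = arena)
  attr(traj, "states") <- factor(SIM_STATES[sim$state + 1L],
                                 levels = SIM_STATES)
  traj
}
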