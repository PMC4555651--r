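METRICS <- c("distance_cm", "ipsi_turns", "contra_turns",
             "stretched_time_s", "space_occupancy_cm")

#' Effect model for one behavioural metric
#'
#' Defines the expected value of a metric in each cell of the 2 x 4
#' factorial design as `baseline + toz + rad[j] + interaction pattern`,
#' plus a Gaussian per-animal residual.  The `interaction` value is the
#' sum-to-zero interaction coefficient of the combination cell
#' (Tozadenant 30 with the highest Radiprodil dose): the single-cell
#' synergy bump is projected onto the pure-interaction space and rescaled
#' so the combination-cell entry equals `interaction`, leaving both
#' factors' marginal means untouched.  `interaction = 0` gives a strictly
#' additive model.
#'
#' @param baseline Expected metric value in the double-vehicle cell.
#' @param toz Main effect of Tozadenant 30 mg/kg.
#' @param rad Length-3 vector of Radiprodil dose effects (1, 2, 3 mg/kg).
#' @param interaction Combination-cell interaction coefficient (see above).
#' @param sd Residual standard deviation of the per-animal metric target.
#' @return A list of class `effect_model` with the 2 x 4 matrix of cell
#'   means as element `cell_means`.
#' @export
effect_model <- function(baseline, toz = 0, rad = c(0, 0, 0),
                         interaction = 0, sd = 1) {
  stopifnot(length(rad) == 3, is.numeric(sd), sd > 0)
  gam <- interaction *
    rbind(c(1 / 3, 1 / 3, 1 / 3, -1),
          c(-1 / 3, -1 / 3, -1 / 3, 1))
  mu <- outer(c(0, toz), c(0, rad), "+") + baseline + gam
  dimnames(mu) <- list(toz = c("0", "30"), rad = c("0", "1", "2", "3"))
  structure(list(baseline = baseline, toz = toz, rad = rad,
                 interaction = interaction, sd = sd, cell_means = mu),
            class = "effect_model")
}

#' Cohort specification for the factorial simulator
#'
#' Describes a full synthetic study: per-metric [effect_model()]s, the
#' per-cell sample size and the session geometry.  Drug effects are
#' injected at the phenotype-parameter level (walking speed for distance,
#' circling-state occupancy and direction bias for turn counts, per-bout
#' stretched-posture probability for stretched time) so that the whole
#' scoring pipeline, not only the statistics, is exercised.  Space
#' occupancy is emergent from the kinematics and cannot be mean-targeted;
#' supplying an effect model for it is an error.
#'
#' @param effects Named list of [effect_model()]s; names from
#'   `distance_cm`, `ipsi_turns`, `contra_turns`, `stretched_time_s`.
#' @param n_per_cell Animals per factorial cell (default 8).
#' @param duration,rate Session length (s) and sampling rate (Hz).
#' @param seed Integer master seed; per-animal substreams are derived from
#'   it.
#' @param include_comparators Also simulate the two L-Dopa comparator
#'   groups (`n_per_cell` each) with their default phenotypes.
#' @param turn_rate,circle_radius Circling kinematics used when turn-count
#'   targets are mapped to circling occupancy.
#' @param rest_frac Expected fraction of the session spent resting.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(effects, n_per_cell = 8, duration = 3300, rate = 25,
                        seed = NULL, include_comparators = FALSE,
                        turn_rate = 60, circle_radius = 6, rest_frac = 0.1) {
  if (!is.list(effects) || is.null(names(effects)))
    stop("effects must be a named list of effect_model objects")
  if ("space_occupancy_cm" %in% names(effects))
    stop("space occupancy is emergent from the kinematics and cannot be ",
         "targeted by an effect model")
  allowed <- c("distance_cm", "ipsi_turns", "contra_turns", "stretched_time_s")
  bad <- setdiff(names(effects), allowed)
  if (length(bad)) stop("unsupported effect-model metrics: ",
                        paste(bad, collapse = ", "))
  for (m in names(effects)) {
    if (!inherits(effects[[m]], "effect_model"))
      stop("effects$", m, " is not an effect_model")
    if (any(effects[[m]]$cell_means < 0))
      stop("effect model for ", m, " implies a negative expected metric")
  }
  if (n_per_cell < 2) stop("n_per_cell must be at least 2")
  structure(list(effects = effects, n_per_cell = n_per_cell,
                 duration = duration, rate = rate, seed = seed,
                 include_comparators = include_comparators,
                 turn_rate = turn_rate, circle_radius = circle_radius,
                 rest_frac = rest_frac),
            class = "cohort_spec")
}

# Build the per-animal phenotype realising the drawn metric targets.
targeted_phenotype <- function(spec, targets) {
  dur <- spec$duration
  omega <- spec$turn_rate
  circ_speed <- spec$circle_radius * omega * pi / 180

  f_ccw <- if (!is.na(targets["ipsi_turns"]))
    max(0, targets[["ipsi_turns"]]) * 360 / omega / dur else 0
  f_cw <- if (!is.na(targets["contra_turns"]))
    max(0, targets[["contra_turns"]]) * 360 / omega / dur else 0
  f_rest <- spec$rest_frac
  f_walk <- 1 - f_rest - f_ccw - f_cw
  if (f_walk < 0.05)
    stop("effect model implies infeasible state occupancy ",
         "(circling would fill the session)")

  walk_speed <- 10
  if (!is.na(targets["distance_cm"])) {
    d_circ <- (f_ccw + f_cw) * dur * circ_speed
    walk_speed <- (max(0, targets[["distance_cm"]]) - d_circ) / (f_walk * dur)
    if (walk_speed <= 0.2)
      stop("effect model implies a negative expected walking distance")
  }

  stretch_prob <- -1
  if (!is.na(targets["stretched_time_s"]))
    stretch_prob <- min(1, max(0, targets[["stretched_time_s"]] / dur))

  dwell <- c(4, 10, 8, 8, 8)
  f <- c(f_rest, f_walk, f_ccw, f_cw, 0)
  q <- ifelse(f > 0, f / dwell, 0)
  q <- q / sum(q)
  phenotype_config(
    "mono_like",
    dwell = dwell,
    trans = matrix(rep(q, 5), nrow = 5, byrow = TRUE,
                   dimnames = list(SIM_STATES, SIM_STATES)),
    circling_bias = if (f_ccw + f_cw > 0) f_ccw / (f_ccw + f_cw) else 0.5,
    turn_rate = omega, circle_radius = spec$circle_radius,
    speed_mean = c(0, walk_speed, NA, NA, walk_speed),
    speed_sd = c(0, 0.2, 0.1, 0.1, 0.2),
    heading_sd = c(2, 3, 0, 0, 3),
    # low-noise tracking model: keeps the injected cell means identifiable
    # in the scored metrics (the 1-cm gate inflates distance under jitter)
    jitter_sd = 0.05,
    stretch_prob = stretch_prob)
}

#' Simulate a full factorial cohort
#'
#' Draws per-animal metric targets from the cell means of each
#' [effect_model()] in the spec, maps them to phenotype parameters, and
#' simulates every session.  The realised per-cell metric means converge to
#' the model means as the per-cell sample size grows.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `cohort` (a `cohort_table`) and
#'   `trajectories` (named list of [trajectory()] objects, one per animal).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- expand.grid(toz = c(0, 30), rad = c(0, 1, 2, 3))
  n <- spec$n_per_cell
  n_fac <- nrow(cells) * n
  comp_groups <- if (spec$include_comparators)
    c("ldopa_benserazide", "ldopa_25") else character(0)
  n_tot <- n_fac + length(comp_groups) * n

  drawn <- with_seed(spec$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    targets <- matrix(NA_real_, nrow = n_fac, ncol = length(METRICS),
                      dimnames = list(NULL, METRICS))
    for (m in names(spec$effects)) {
      em <- spec$effects[[m]]
      k <- 0L
      for (ci in seq_len(nrow(cells))) {
        mu <- em$cell_means[as.character(cells$toz[ci]),
                            as.character(cells$rad[ci])]
        targets[k + seq_len(n), m] <- rnorm(n, mu, em$sd)
        k <- k + n
      }
    }
    list(seeds = seeds, targets = targets)
  })

  rows <- list(); trajs <- list()
  a <- 0L
  for (ci in seq_len(nrow(cells))) {
    toz <- cells$toz[ci]; rad <- cells$rad[ci]
    label <- paste0(if (toz > 0) "TOZ" else "", if (toz > 0 && rad > 0) "_" else "",
                    if (rad > 0) paste0("RAD", rad) else "")
    if (label == "") label <- "VEH"
    for (k in seq_len(n)) {
      a <- a + 1L
      id <- sprintf("A%03d", a)
      cfg <- targeted_phenotype(spec, drawn$targets[a, ])
      trajs[[id]] <- simulate_session(cfg, duration = spec$duration,
                                      rate = spec$rate,
                                      seed = drawn$seeds[a], animal_id = id)
      rows[[a]] <- data.frame(animal_id = id, group_label = label,
                              toz_dose = toz, rad_dose = rad,
                              comparator = "none", lesion_side = "right")
    }
  }
  for (g in comp_groups) {
    cfg <- phenotype_config(if (g == "ldopa_benserazide") "ldopa_ben_like"
                            else "ldopa25_like")
    for (k in seq_len(n)) {
      a <- a + 1L
      id <- sprintf("A%03d", a)
      trajs[[id]] <- simulate_session(cfg, duration = spec$duration,
                                      rate = spec$rate,
                                      seed = drawn$seeds[a], animal_id = id)
      rows[[a]] <- data.frame(animal_id = id,
                              group_label = toupper(g),
                              toz_dose = 0, rad_dose = 0,
                              comparator = g, lesion_side = "right")
    }
  }
  cohort <- cohort_table(do.call(rbind, rows), n_expected = n)
  list(cohort = cohort, trajectories = trajs)
}
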