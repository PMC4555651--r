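# Programmatic fixtures: trajectories built from analytic centre paths and
# small CSV files written to tempdirs.

BIG_ARENA <- arena_spec(width = 200, height = 200)

# Build a trajectory from a centre path, with the body axis following the
# path's heading (or a supplied angle sequence, degrees).
traj_from_path <- function(x, y, rate = 25, heading_deg = NULL,
                           nose_len = 9, tail_len = 11, elong = 1,
                           arena = BIG_ARENA, animal_id = "fixture") {
  n <- length(x)
  if (is.null(heading_deg)) {
    heading_deg <- atan2(c(diff(y), 0), c(diff(x), 0)) * 180 / pi
    if (n > 1) heading_deg[n] <- heading_deg[n - 1]
  }
  u <- heading_deg * pi / 180
  fr <- data.frame(t = (seq_len(n) - 1) / rate,
                   nose_x = x + elong * nose_len * cos(u),
                   nose_y = y + elong * nose_len * sin(u),
                   centre_x = x, centre_y = y,
                   tail_x = x - elong * tail_len * cos(u),
                   tail_y = y - elong * tail_len * sin(u))
  trajectory(fr, rate = rate, animal_id = animal_id, arena = arena)
}

# Centre moving on a circle; body axis tangent to it.
circle_traj <- function(radius = 5, omega_deg = 36, duration = 60, rate = 25,
                        ccw = TRUE, centre = c(100, 100), arena = BIG_ARENA) {
  tt <- (seq_len(round(duration * rate)) - 1) / rate
  ang <- (if (ccw) 1 else -1) * omega_deg * pi / 180 * tt
  x <- centre[1] + radius * cos(ang)
  y <- centre[2] + radius * sin(ang)
  heading <- ang * 180 / pi + (if (ccw) 90 else -90)
  traj_from_path(x, y, rate = rate, heading_deg = heading, arena = arena)
}

# Smooth random walk with noisy body axis, for oracle-equivalence tests.
random_traj <- function(n = 800, rate = 25, seed = 1) {
  set.seed(seed)
  heading <- cumsum(rnorm(n, 0, 12))
  step <- pmax(0, rnorm(n, 0.25, 0.15))
  x <- 100 + cumsum(step * cos(heading * pi / 180))
  y <- 100 + cumsum(step * sin(heading * pi / 180))
  x <- pmin(pmax(x, 20), 180); y <- pmin(pmax(y, 20), 180)
  body <- heading + rnorm(n, 0, 8)
  traj_from_path(x, y, rate = rate, heading_deg = body)
}

write_traj_csv <- function(df, path = tempfile(fileext = ".csv")) {
  stopifnot(identical(names(df),
                      c("time_s", "nose_x", "nose_y", "centre_x", "centre_y",
                        "tail_x", "tail_y")))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

simple_traj_df <- function(n = 5, rate = 25) {
  tt <- (seq_len(n) - 1) / rate
  data.frame(time_s = tt,
             nose_x = 10 + tt, nose_y = 10,
             centre_x = 8 + tt, centre_y = 10,
             tail_x = 6 + tt, tail_y = 10)
}

# Balanced factorial manifest data frame.
manifest_df <- function(n_per_cell = 8) {
  cells <- expand.grid(toz = c(0, 30), rad = 0:3)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(toz_dose = cells$toz[i], rad_dose = cells$rad[i],
               n = seq_len(n_per_cell))
  }))
  data.frame(animal_id = sprintf("R%03d", seq_len(nrow(rows))),
             group_label = paste0("T", rows$toz_dose, "R", rows$rad_dose),
             toz_dose = rows$toz_dose, rad_dose = rows$rad_dose,
             comparator = "none", lesion_side = "right")
}

# Balanced 2x4 metric table with given cell means and iid residuals.
metric_tab_from_means <- function(mu, n = 8, sd = 1, metric = "distance_cm",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(toz = c(0, 30), rad = 0:3)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- mu[ifelse(cells$toz[i] == 0, 1, 2), cells$rad[i] + 1]
    data.frame(animal_id = paste0("c", i, "_", seq_len(n)),
               toz_level = cells$toz[i], rad_level = cells$rad[i],
               metric = metric, value = m + rnorm(n, 0, sd))
  })
  do.call(rbind, rows)
}

# Mirror a trajectory about the vertical axis x = const.
mirror_traj <- function(traj, about = 100) {
  fr <- traj$frames
  for (cc in c("nose_x", "centre_x", "tail_x")) fr[[cc]] <- 2 * about - fr[[cc]]
  trajectory(fr, rate = traj$rate, animal_id = traj$animal_id,
             arena = traj$arena)
}
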