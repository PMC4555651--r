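test_that("distance accumulates gated centre displacements", {
  # single accepted 3-4-5 step
  tr <- traj_from_path(c(100, 103), c(100, 104), rate = 25)
  expect_equal(compute_distance(tr, min_step = 1), 5)

  # perfectly stationary
  tr0 <- traj_from_path(rep(100, 200), rep(100, 200))
  expect_equal(compute_distance(tr0, min_step = 1), 0)
})

test_that("the 1-cm gate suppresses stationary jitter entirely", {
  set.seed(42)
  x <- 100 + rnorm(2000, 0, 0.1); y <- 100 + rnorm(2000, 0, 0.1)
  tr <- traj_from_path(x, y)
  o <- oracle_gate(x, y, rep(TRUE, 2000), 1)
  expect_equal(compute_distance(tr, min_step = 1), o$distance)
  expect_equal(o$distance, 0)
})

test_that("gated distance matches the sample-by-sample oracle on rough paths", {
  for (seed in 1:5) {
    tr <- random_traj(n = 600, seed = seed)
    fr <- tr$frames
    o <- oracle_gate(fr$centre_x, fr$centre_y, fr$valid, 1)
    expect_equal(compute_distance(tr, min_step = 1), o$distance)
  }
})

test_that("full circles are counted with the correct direction labels", {
  # 3 complete CCW circles, right lesion, from below -> ipsi
  tr <- circle_traj(radius = 5, omega_deg = 36, duration = 30.4)  # 3.04 revs
  expect_equal(count_turns(tr), c(ipsi = 3, contra = 0))

  # clockwise -> contra
  tr_cw <- circle_traj(radius = 5, omega_deg = 36, duration = 30.4, ccw = FALSE)
  expect_equal(count_turns(tr_cw), c(ipsi = 0, contra = 3))

  # label mapping flips with lesion side and with camera view, not geometry
  expect_equal(count_turns(tr, turn_params(lesion_side = "left")),
               c(ipsi = 0, contra = 3))
  expect_equal(count_turns(tr, turn_params(view = "from-above")),
               c(ipsi = 0, contra = 3))
  expect_equal(count_turns(tr, turn_params(lesion_side = "left",
                                           view = "from-above")),
               c(ipsi = 3, contra = 0))
})

test_that("mirror reflection swaps ipsi and contra counts", {
  for (seed in c(2, 9, 17)) {
    tr <- random_traj(n = 700, seed = seed)
    a <- count_turns(tr)
    b <- count_turns(mirror_traj(tr))
    expect_equal(unname(a), unname(rev(b)))
  }
})

test_that("stationary jitter yields no turns", {
  set.seed(1)
  tr <- traj_from_path(100 + rnorm(500, 0, 0.05), 100 + rnorm(500, 0, 0.05))
  expect_equal(count_turns(tr), c(ipsi = 0, contra = 0))
})

test_that("turn counts match the brute-force integrator on random paths", {
  for (seed in 1:20) {
    tr <- random_traj(n = 1000, seed = seed)
    got <- count_turns(tr)
    want <- oracle_turns(tr)
    expect_identical(unname(got), as.integer(unname(want)))
  }
})

test_that("stretched time thresholds elongation against the reference", {
  n <- 500
  # constant full elongation with a fixed reference equal to body length
  tr <- traj_from_path(50 + (seq_len(n) - 1) * 0.2, rep(100, n), elong = 1)
  pp <- posture_params(reference = "fixed-length", fixed_length = 20)
  expect_equal(stretched_time(tr, pp), n / 25)

  # constant elongation 0.5 below the 0.7 threshold
  tr2 <- traj_from_path(50 + (seq_len(n) - 1) * 0.2, rep(100, n), elong = 0.5)
  expect_equal(stretched_time(tr2, pp), 0)
})

test_that("alternating posture is scored frame by frame", {
  n <- 400
  x <- 100 + (seq_len(n) - 1) * 0.2
  elong <- ifelse(seq_len(n) %% 2 == 0, 0.9, 0.5)
  u <- 0
  fr <- data.frame(t = (seq_len(n) - 1) / 25,
                   nose_x = x + elong * 9, nose_y = 100,
                   centre_x = x, centre_y = 100,
                   tail_x = x - elong * 11, tail_y = 100)
  tr <- trajectory(fr, rate = 25, arena = BIG_ARENA)
  pp <- posture_params(reference = "fixed-length", fixed_length = 20)
  # oracle: count frames at or above threshold
  d <- sqrt((fr$nose_x - fr$tail_x)^2 + (fr$nose_y - fr$tail_y)^2)
  want <- sum(d / 20 >= 0.7) / 25
  expect_equal(stretched_time(tr, pp), want)
  expect_equal(want, (n / 2) / 25)
})

test_that("a degenerate elongation reference is an error", {
  tr <- traj_from_path(rep(100, 300), rep(100, 300), elong = 1)
  fr <- tr$frames
  fr$nose_x <- fr$centre_x; fr$nose_y <- fr$centre_y
  fr$tail_x <- fr$centre_x; fr$tail_y <- fr$centre_y
  tr0 <- trajectory(fr, rate = 25, arena = BIG_ARENA)
  expect_error(stretched_time(tr0), "reference")
})

test_that("gyration radius hits the analytic limits", {
  # circle of radius 5, exactly one revolution per 10-s bin
  tr <- circle_traj(radius = 5, omega_deg = 36, duration = 60)
  expect_equal(as.numeric(gyration_radius(tr)), 5, tolerance = 1e-9)

  # stationary point
  tr0 <- traj_from_path(rep(100, 250), rep(100, 250))
  expect_equal(as.numeric(gyration_radius(tr0)), 0)

  # constant-speed straight run of 20 cm inside one bin: L/4
  n <- 250
  tr_line <- traj_from_path(100 + 20 * (seq_len(n) - 1) / (n - 1), rep(100, n))
  expect_equal(as.numeric(gyration_radius(tr_line)), 5, tolerance = 0.02)
})

test_that("gyration radius matches direct per-bin recomputation", {
  for (seed in c(4, 11)) {
    tr <- random_traj(n = 1000, seed = seed)
    expect_equal(as.numeric(gyration_radius(tr)), oracle_gyration(tr),
                 tolerance = 1e-9)
  }
})

test_that("sparse bins are excluded, not renormalised", {
  tr <- circle_traj(radius = 5, omega_deg = 36, duration = 30)
  fr <- tr$frames
  fr$valid[260:500] <- FALSE   # second bin falls below 80% valid
  tr2 <- trajectory(fr, rate = 25, arena = tr$arena)
  g <- gyration_radius(tr2, qc_limit = 0.5)
  expect_equal(attr(g, "excluded_bins"), 2)
  expect_equal(as.numeric(g), 5, tolerance = 1e-6)
  fr$valid[] <- FALSE
  tr3 <- trajectory(fr, rate = 25, arena = tr$arena)
  tr3$frames$valid <- FALSE
  expect_error(gyration_radius(tr3, qc_limit = 2), "usable")
})

test_that("metrics are invariant under rigid motions and equivariant under scaling", {
  base <- random_traj(n = 800, seed = 21)
  d0 <- compute_distance(base); t0 <- count_turns(base)
  g0 <- as.numeric(gyration_radius(base))
  pp <- posture_params(reference = "fixed-length", fixed_length = 20)
  s0 <- stretched_time(base, pp)

  rigid <- function(tr, ang, dx, dy) {
    fr <- tr$frames; R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    for (pt in c("nose", "centre", "tail")) {
      xy <- as.matrix(fr[, paste0(pt, c("_x", "_y"))]) %*% t(R)
      fr[[paste0(pt, "_x")]] <- xy[, 1] + dx
      fr[[paste0(pt, "_y")]] <- xy[, 2] + dy
    }
    trajectory(fr, rate = tr$rate, arena = arena_spec(width = 500, height = 500))
  }
  tr1 <- rigid(base, 0.7, 40, 25)
  expect_equal(compute_distance(tr1), d0, tolerance = 1e-9)
  expect_equal(count_turns(tr1), t0)
  expect_equal(as.numeric(gyration_radius(tr1)), g0, tolerance = 1e-9)
  expect_equal(stretched_time(tr1, pp), s0)

  # scaling by c scales lengths by c when the gate and reference scale too
  cc <- 2.5
  frs <- base$frames
  for (col in c("nose_x", "nose_y", "centre_x", "centre_y", "tail_x", "tail_y"))
    frs[[col]] <- frs[[col]] * cc
  trs <- trajectory(frs, rate = base$rate,
                    arena = arena_spec(width = 500, height = 500))
  expect_equal(compute_distance(trs, min_step = cc), cc * d0, tolerance = 1e-9)
  expect_equal(count_turns(trs, turn_params(min_step = cc)), t0)
  expect_equal(as.numeric(gyration_radius(trs)), cc * g0, tolerance = 1e-9)
  pps <- posture_params(reference = "fixed-length", fixed_length = 20 * cc)
  expect_equal(stretched_time(trs, pps), s0)
})

test_that("space occupancy is bounded by the arena geometry", {
  for (seed in c(3, 13)) {
    tr <- random_traj(n = 1000, seed = seed)
    g <- as.numeric(gyration_radius(tr))
    diag_len <- sqrt(tr$arena$width^2 + tr$arena$height^2)
    expect_lte(g, diag_len / 2)
  }
})

test_that("score_animal assembles all five metrics and enforces QC", {
  circ <- circle_traj(radius = 5, omega_deg = 60, duration = 123,
                      ccw = FALSE)
  s <- score_animal(circ)
  expect_s3_class(s, "behaviour_summary")
  expect_equal(s$contra_turns, 20)   # floor(60 deg/s * 123 s / 360)
  expect_equal(s$ipsi_turns, 0)
  expect_lt(s$space_occupancy_cm, 6)   # bounded near the circle radius

  # stationary session: all zero except posture
  tr0 <- traj_from_path(rep(100, 500), rep(100, 500), elong = 1)
  pp <- posture_params(reference = "fixed-length", fixed_length = 20)
  s0 <- score_animal(tr0, posture = pp)
  expect_equal(s0$distance_cm, 0)
  expect_equal(s0$ipsi_turns + s0$contra_turns, 0)
  expect_equal(s0$space_occupancy_cm, 0)
  expect_equal(s0$stretched_time_s, 20)

  # straight exploration roams more than circling
  straight <- random_traj(n = 3000, seed = 8)
  expect_gt(as.numeric(gyration_radius(straight)), s$space_occupancy_cm)

  # QC gate refuses heavily untracked sessions
  fr <- circ$frames; fr$valid[1:500] <- FALSE
  bad <- trajectory(fr, rate = 25, arena = circ$arena)
  bad$frames$valid[1:500] <- FALSE
  bad$invalid_fraction <- mean(!bad$frames$valid)
  expect_error(score_animal(bad), "QC")
})
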