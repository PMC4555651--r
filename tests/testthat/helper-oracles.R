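# Independent pure-R oracles, written directly from the documented rules.
# They replay every sample sequentially and are deliberately kept separate
# from the package's vectorised/C++ code paths.

# Minimal-distance gate, replayed sample by sample.  Returns accepted frame
# indices, a segment id per accepted frame (segments break across
# non-interpolated invalid runs), and the gated distance.
oracle_gate <- function(x, y, valid, min_step) {
  idx <- integer(0); seg_id <- integer(0)
  dist <- 0; seg <- 0L
  anchor <- NULL; in_gap <- FALSE
  for (i in seq_along(x)) {
    if (!valid[i]) { if (!is.null(anchor)) in_gap <- TRUE; next }
    if (is.null(anchor) || in_gap) {
      anchor <- c(x[i], y[i]); in_gap <- FALSE
      seg <- seg + 1L
      idx <- c(idx, i); seg_id <- c(seg_id, seg)
      next
    }
    d <- sqrt((x[i] - anchor[1])^2 + (y[i] - anchor[2])^2)
    if (d >= min_step) {
      dist <- dist + d
      anchor <- c(x[i], y[i])
      idx <- c(idx, i); seg_id <- c(seg_id, seg)
    }
  }
  list(distance = dist, accepted = idx, segment = seg_id)
}

oracle_wrap180 <- function(d) {
  d <- d - 360 * floor((d + 180) / 360)
  if (d == -180) d <- 180
  d
}

# Brute-force cumulative-angle integrator: adds the wrapped body-axis angle
# increment to a signed accumulator, counts each +/-360 crossing, and zeroes
# the accumulator after more than `tol` degrees of retreat from its extreme.
oracle_turns_from_angles <- function(theta, segment, tol = 45) {
  ccw <- 0L; cw <- 0L
  acc <- 0; ext <- 0
  for (k in seq_along(theta)[-1]) {
    if (segment[k] != segment[k - 1]) { acc <- 0; ext <- 0; next }
    acc <- acc + oracle_wrap180(theta[k] - theta[k - 1])
    while (acc >= 360) { ccw <- ccw + 1L; acc <- acc - 360; ext <- acc }
    while (acc <= -360) { cw <- cw + 1L; acc <- acc + 360; ext <- acc }
    if (abs(acc) > abs(ext)) ext <- acc
    if ((ext > 0 && ext - acc > tol) || (ext < 0 && acc - ext > tol)) {
      acc <- 0; ext <- 0
    }
  }
  c(ccw = ccw, cw = cw)
}

# Full oracle turn counter over a trajectory (image-frame ccw/cw counts).
oracle_turns <- function(traj, min_step = 1, tol = 45) {
  fr <- traj$frames
  g <- oracle_gate(fr$centre_x, fr$centre_y, fr$valid, min_step)
  dx <- fr$nose_x[g$accepted] - fr$centre_x[g$accepted]
  dy <- fr$nose_y[g$accepted] - fr$centre_y[g$accepted]
  keep <- sqrt(dx^2 + dy^2) > 1e-9
  theta <- atan2(dy[keep], dx[keep]) * 180 / pi
  oracle_turns_from_angles(theta, g$segment[keep], tol)
}

# Direct per-bin recomputation of the mean gyration radius.
oracle_gyration <- function(traj, bin = 10, min_valid_frac = 0.8) {
  fr <- traj$frames
  per_bin <- round(bin * traj$rate)
  nbin <- nrow(fr) %/% per_bin
  radii <- c()
  for (b in seq_len(nbin)) {
    i <- ((b - 1) * per_bin + 1):(b * per_bin)
    ok <- fr$valid[i]
    if (mean(ok) < min_valid_frac) next
    px <- fr$centre_x[i][ok]; py <- fr$centre_y[i][ok]
    cx <- mean(px); cy <- mean(py)
    radii <- c(radii, mean(sqrt((px - cx)^2 + (py - cy)^2)))
  }
  mean(radii)
}

# Closed-form balanced two-way ANOVA from cell and grand means.
oracle_anova_ss <- function(value, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(value) / (nlevels(a) * nlevels(b))
  gm <- mean(value)
  am <- tapply(value, a, mean); bm <- tapply(value, b, mean)
  cm <- tapply(value, interaction(a, b), mean)
  ss_a <- n * nlevels(b) * sum((am - gm)^2)
  ss_b <- n * nlevels(a) * sum((bm - gm)^2)
  ss_cells <- n * sum((cm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((value - gm)^2)
  ss_err <- ss_tot - ss_cells
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_err <- length(value) - nlevels(a) * nlevels(b)
  list(ss = c(a = ss_a, b = ss_b, ab = ss_ab, err = ss_err, tot = ss_tot),
       F = c(a = (ss_a / df_a) / (ss_err / df_err),
             b = (ss_b / df_b) / (ss_err / df_err),
             ab = (ss_ab / df_ab) / (ss_err / df_err)),
       df = c(a = df_a, b = df_b, ab = df_ab, err = df_err))
}

# Pooled two-sample t statistic by direct formula.
oracle_pooled_t <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Coarse-grid Box-Cox profile log-likelihood, independent of MASS.
oracle_boxcox_lambda <- function(y, groups, grid = seq(-2, 2, 0.05)) {
  n <- length(y)
  ll <- sapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    res <- z - ave(z, groups)
    -n / 2 * log(sum(res^2) / n) + (lam - 1) * sum(log(y))
  })
  grid[which.max(ll)]
}
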