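flat_mu <- matrix(10, 2, 4)

test_that("homoscedastic Gaussian cells need no transformation", {
  tab <- metric_tab_from_means(flat_mu + outer(c(0, 3), c(0, 1, 2, 3)),
                               n = 10, sd = 1, seed = 101)
  res <- check_and_transform(tab)
  expect_equal(res$record$transform, "none")
  expect_gte(res$record$levene_p, 0.05)
  expect_identical(res$table$value, tab$value)
})

test_that("sd proportional to mean selects the log transform", {
  set.seed(77)
  cells <- expand.grid(toz = c(0, 30), rad = 0:3)
  mu <- c(1, 2, 4, 8, 16, 32, 64, 128)
  tab <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(animal_id = paste0("c", i, "_", 1:12),
               toz_level = cells$toz[i], rad_level = cells$rad[i],
               metric = "distance_cm",
               value = exp(log(mu[i]) + rnorm(12, 0, 0.5)))
  }))
  res <- check_and_transform(tab)
  expect_equal(res$record$transform, "log")
  lam_oracle <- oracle_boxcox_lambda(
    tab$value, interaction(tab$toz_level, tab$rad_level))
  expect_equal(res$record$lambda, lam_oracle, tolerance = 0.1)
  expect_lt(abs(lam_oracle), 0.25)
})

test_that("Poisson-like counts select the square-root transform", {
  set.seed(55)
  cells <- expand.grid(toz = c(0, 30), rad = 0:3)
  mu <- c(2, 5, 10, 20, 40, 80, 160, 320)
  tab <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(animal_id = paste0("c", i, "_", 1:15),
               toz_level = cells$toz[i], rad_level = cells$rad[i],
               metric = "contra_turns",
               value = rpois(15, mu[i]))
  }))
  res <- check_and_transform(tab)
  expect_equal(res$record$transform, "sqrt")
  off <- if (any(tab$value == 0)) 1 else 0
  lam_oracle <- oracle_boxcox_lambda(
    tab$value + off, interaction(tab$toz_level, tab$rad_level))
  expect_gte(lam_oracle, 0.2)
  expect_lt(lam_oracle, 0.8)
})

test_that("transform selection is invariant to positive rescaling", {
  set.seed(88)
  cells <- expand.grid(toz = c(0, 30), rad = 0:3)
  mu <- c(1, 2, 4, 8, 16, 32, 64, 128)
  tab <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(animal_id = paste0("c", i, "_", 1:10),
               toz_level = cells$toz[i], rad_level = cells$rad[i],
               metric = "distance_cm",
               value = exp(log(mu[i]) + rnorm(10, 0, 0.4)))
  }))
  r1 <- check_and_transform(tab)
  tab2 <- tab; tab2$value <- tab$value * 37.5
  r2 <- check_and_transform(tab2)
  expect_equal(r1$record$transform, r2$record$transform)
})

test_that("degenerate and non-finite inputs are rejected", {
  tab <- metric_tab_from_means(flat_mu, n = 3, sd = 1, seed = 1)
  tab$value <- 5
  expect_error(check_and_transform(tab), "equal")
  tab$value <- c(Inf, rep(1, nrow(tab) - 1))
  expect_error(check_and_transform(tab), "finite")
})

test_that("identical cell means give vanishing effect F statistics", {
  tab <- metric_tab_from_means(flat_mu, n = 2, sd = 1, seed = 9)
  # force every cell to the same pair of values: means identical, but
  # residual variance positive
  tab$value <- rep(c(9, 11), nrow(tab) / 2)
  an <- two_way_anova(tab)
  expect_equal(an$effects$F[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(an$mode, "additive")
})

test_that("ANOVA matches the closed-form sums-of-squares oracle", {
  # hand-sized balanced 2x2 with n = 2 and integer values
  df <- data.frame(animal_id = paste0("a", 1:8),
                   toz_level = rep(c(0, 0, 30, 30), 2),
                   rad_level = rep(c(0, 1), each = 4),
                   metric = "distance_cm",
                   value = c(3, 5, 10, 14, 6, 8, 9, 13))
  an <- two_way_anova(df)
  o <- oracle_anova_ss(df$value, df$toz_level, df$rad_level)
  eff <- an$effects
  expect_equal(eff$sumsq[eff$term == "toz"], unname(o$ss["a"]), tolerance = 1e-12)
  expect_equal(eff$sumsq[eff$term == "rad"], unname(o$ss["b"]), tolerance = 1e-12)
  expect_equal(eff$sumsq[eff$term == "toz:rad"], unname(o$ss["ab"]), tolerance = 1e-12)
  expect_equal(eff$F[eff$term == "toz"], unname(o$F["a"]), tolerance = 1e-12)
  expect_equal(eff$F[eff$term == "toz:rad"], unname(o$F["ab"]), tolerance = 1e-12)
})

test_that("the balanced sums-of-squares identity holds on random designs", {
  for (seed in 1:25) {
    tab <- metric_tab_from_means(matrix(rnorm(8, 10, 3), 2, 4), n = 5,
                                 sd = runif(1, 0.5, 3), seed = 200 + seed)
    an <- two_way_anova(tab)
    o <- oracle_anova_ss(tab$value, tab$toz_level, tab$rad_level)
    expect_equal(sum(an$effects$sumsq), unname(o$ss["tot"]),
                 tolerance = 1e-9)
    expect_equal(an$effects$df[an$effects$term == "toz:rad"], 3)
    expect_equal(an$effects$df[an$effects$term == "residuals"],
                 nrow(tab) - 8)
  }
})

test_that("the full-design degrees of freedom match the 2x4, n=8 layout", {
  tab <- metric_tab_from_means(flat_mu + outer(c(0, 2), 0:3), n = 8,
                               sd = 1, seed = 42)
  an <- two_way_anova(tab)
  eff <- an$effects
  expect_equal(eff$df[eff$term == "toz"], 1)
  expect_equal(eff$df[eff$term == "rad"], 3)
  expect_equal(eff$df[eff$term == "toz:rad"], 3)
  # error df = N - cells, as implied by the supplied data (64 - 8)
  expect_equal(eff$df[eff$term == "residuals"], 56)
})

test_that("a 2-level one-way F equals the squared pooled t", {
  set.seed(3)
  a <- rnorm(8, 10, 2); b <- rnorm(8, 12, 2)
  tt <- comparator_ttest(a, b)
  fit <- aov(c(a, b) ~ factor(rep(1:2, each = 8)))
  F_val <- summary(fit)[[1]][1, "F value"]
  expect_equal(tt$t^2, F_val, tolerance = 1e-10)
})

test_that("empty or underfilled cells are informative errors", {
  tab <- metric_tab_from_means(flat_mu, n = 3, sd = 1, seed = 5)
  miss <- tab[!(tab$toz_level == 30 & tab$rad_level == 2), ]
  expect_error(two_way_anova(miss), "empty design cell: toz=30, rad=2")
  single <- tab[tab$rad_level == 0, ]
  expect_error(two_way_anova(single), "2 levels")
})

test_that("Tukey comparisons cover all 28 cell pairs", {
  tab <- metric_tab_from_means(flat_mu + outer(c(0, 4), 0:3), n = 8,
                               sd = 1, seed = 7)
  tk <- tukey_hsd(tab)
  expect_equal(nrow(tk), 28)
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
})

test_that("identically distributed cells give maximal adjusted p", {
  tab <- metric_tab_from_means(flat_mu, n = 3, sd = 1, seed = 1)
  tab$value <- rep(c(1, 2, 3), nrow(tab) / 3)  # same values in every cell
  tk <- tukey_hsd(tab)
  expect_equal(tk$p_adj, rep(1, 28))
  expect_false(any(tk$significant))
})

test_that("a strongly shifted cell is significant against every other", {
  tab <- metric_tab_from_means(flat_mu, n = 8, sd = 1, seed = 12)
  shift <- tab$toz_level == 30 & tab$rad_level == 3
  tab$value[shift] <- tab$value[shift] + 10
  tk <- tukey_hsd(tab)
  hit <- grepl("T30.R3", tk$comparison, fixed = TRUE)
  expect_equal(sum(hit), 7)
  expect_true(all(tk$significant[hit]))
})

test_that("Tukey adjusted p dominates the unadjusted pairwise comparison", {
  tab <- metric_tab_from_means(flat_mu + outer(c(0, 1.5), 0:3), n = 6,
                               sd = 1.2, seed = 31)
  tk <- tukey_hsd(tab)
  cell <- paste0("T", tab$toz_level, ".R", tab$rad_level)
  # unadjusted pairwise p on the shared error mean square
  fit <- aov(tab$value ~ factor(cell))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  df_err <- summary(fit)[[1]]["Residuals", "Df"]
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(tk$comparison[i], "-", fixed = TRUE)[[1]]
    n1 <- sum(cell == pair[1]); n2 <- sum(cell == pair[2])
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    p_t <- 2 * pt(-abs(tk$diff[i]) / se, df_err)
    expect_gte(tk$p_adj[i] + 1e-12, p_t)
  }
})

test_that("the comparator t-test matches the closed-form pooled statistic", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  tt <- comparator_ttest(a, b)
  expect_equal(tt$t, oracle_pooled_t(a, b), tolerance = 1e-12)
  expect_equal(tt$df, 8)

  # identical samples: t = 0, p = 1
  z <- c(1, 2, 3)
  t0 <- comparator_ttest(z, z)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)

  # antisymmetry
  rev_tt <- comparator_ttest(b, a)
  expect_equal(rev_tt$t, -tt$t)
  expect_equal(rev_tt$p, tt$p)

  expect_error(comparator_ttest(c(2, 2), c(2, 2)), "pooled variance")
  expect_error(comparator_ttest(1, c(1, 2)), "at least 2")
})

test_that("synergy_report requires all five metrics and is deterministic", {
  spec <- cohort_spec(
    effects = list(distance_cm = effect_model(2000, 400, c(100, 200, 300),
                                              interaction = 0, sd = 250)),
    n_per_cell = 4, duration = 120, seed = 6)
  sim <- simulate_cohort(spec)
  summ <- score_cohort(sim$trajectories, sim$cohort)
  tab <- metric_table(summ, sim$cohort)
  rep1 <- synergy_report(tab)
  rep2 <- synergy_report(tab)
  expect_identical(rep1, rep2)
  expect_named(rep1$metrics, c("distance_cm", "ipsi_turns", "contra_turns",
                               "stretched_time_s", "space_occupancy_cm"))
  expect_error(synergy_report(tab[tab$metric != "distance_cm", ]),
               "missing")
})
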