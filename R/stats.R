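#' Build the long metric table for the factorial analysis
#'
#' Joins per-animal behaviour summaries with the cohort manifest and
#' returns one row per animal per metric, restricted to the factorial
#' animals (comparator groups are analysed separately with t-tests).
#'
#' @param summaries Data frame from [score_animal()]/[read_summaries()].
#' @param cohort A `cohort_table` (see [read_cohort()]).
#' @return Data frame of class `metric_table` with columns `animal_id`,
#'   `toz_level`, `rad_level`, `metric`, `value`.
#' @export
metric_table <- function(summaries, cohort) {
  summaries <- as.data.frame(summaries)
  fac <- cohort[cohort$comparator == "none", ]
  merged <- merge(fac[, c("animal_id", "toz_dose", "rad_dose")],
                  summaries, by = "animal_id")
  if (nrow(merged) == 0L) stop("no factorial animals with summaries")
  out <- do.call(rbind, lapply(METRICS, function(m) {
    data.frame(animal_id = merged$animal_id,
               toz_level = merged$toz_dose, rad_level = merged$rad_dose,
               metric = m, value = merged[[m]])
  }))
  structure(out, class = c("metric_table", "data.frame"))
}

one_metric <- function(tab) {
  if (length(unique(tab$metric)) != 1L)
    stop("expected a single-metric table; got ",
         paste(unique(tab$metric), collapse = ", "))
  tab
}

#' Homoscedasticity check and Box-Cox-guided transformation
#'
#' Runs Levene's test for equal variances across the eight design cells.
#' If variance homogeneity is rejected at `alpha`, a Box-Cox profile
#' likelihood estimates lambda on the cell-means model and the value is
#' transformed: log if lambda is nearer 0 (`lambda < cut[1]`, with a +1
#' offset when zeros are present), square root if nearer 1/2
#' (`cut[1] <= lambda < cut[2]`), untransformed otherwise.  Negative
#' values leave the data untransformed (recorded in the log).
#'
#' @param tab A single-metric [metric_table()].
#' @param alpha Significance level for Levene's test (default 0.05).
#' @param cut Lambda decision boundaries, default `c(0.25, 0.75)`.
#' @param center Centring statistic for Levene's test: `"mean"` (the
#'   classical form, default) or `"median"` (Brown-Forsythe).
#' @return List with `table` (transformed values) and `record` (transform
#'   applied, Levene statistic and p, lambda, offset).
#' @export
check_and_transform <- function(tab, alpha = 0.05, cut = c(0.25, 0.75),
                                center = c("mean", "median")) {
  center <- match.arg(center)
  tab <- one_metric(as.data.frame(tab))
  v <- tab$value
  if (any(!is.finite(v))) stop("non-finite metric values")
  if (isTRUE(all.equal(stats::var(v), 0)) || stats::var(v) == 0)
    stop("degenerate input: all metric values are equal")
  cell <- interaction(tab$toz_level, tab$rad_level, drop = TRUE)
  lev <- car::leveneTest(v ~ cell,
                         center = if (center == "mean") mean else stats::median)
  lev_stat <- lev[1, "F value"]; lev_p <- lev[1, "Pr(>F)"]

  rec <- list(transform = "none", levene_stat = lev_stat, levene_p = lev_p,
              lambda = NA_real_, offset = 0)
  if (lev_p < alpha) {
    if (any(v < 0)) {
      rec$transform <- "none"
      rec$note <- "negative values: no power transform applicable"
    } else {
      off <- if (any(v == 0)) 1 else 0
      dd <- data.frame(y = v + off, g = cell)
      bc <- MASS::boxcox(y ~ g, data = dd,
                         lambda = seq(-2, 2, 0.01), plotit = FALSE)
      lam <- bc$x[which.max(bc$y)]
      rec$lambda <- lam
      if (lam < cut[1]) {
        rec$transform <- "log"; rec$offset <- off
        tab$value <- log(v + off)
      } else if (lam < cut[2]) {
        rec$transform <- "sqrt"
        tab$value <- sqrt(v)
      }
    }
  }
  list(table = tab, record = rec)
}

#' Two-way factorial ANOVA with the interaction-as-synergy criterion
#'
#' Fixed-effects decomposition of a metric over Tozadenant (2 levels) and
#' Radiprodil (4 levels), using Type II sums of squares (identical to the
#' classical decomposition for balanced data).  The two drugs are declared
#' to interact in a `synergistic` mode when the interaction term is
#' significant at `alpha`, and an `additive` mode otherwise.
#'
#' @param tab A single-metric [metric_table()].
#' @param alpha Significance level (default 0.05).
#' @return Object of class `anova_synergy`: a list with `effects` (term,
#'   sum of squares, df, F, p), `mode`, `alpha`.
#' @export
two_way_anova <- function(tab, alpha = 0.05) {
  tab <- one_metric(as.data.frame(tab))
  toz <- factor(tab$toz_level); rad <- factor(tab$rad_level)
  if (nlevels(toz) < 2 || nlevels(rad) < 2)
    stop("both factors need at least 2 levels")
  counts <- table(toz, rad)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: toz=%s, rad=%s",
                 rownames(counts)[empty[1]], colnames(counts)[empty[2]]))
  }
  if (any(counts < 2)) stop("every design cell needs at least 2 observations")

  fit <- lm(tab$value ~ toz * rad)
  a2 <- car::Anova(fit, type = 2)
  pick <- function(term) {
    i <- match(term, rownames(a2))
    c(sumsq = a2[i, "Sum Sq"], df = a2[i, "Df"],
      F = a2[i, "F value"], p = a2[i, "Pr(>F)"])
  }
  eff <- rbind(toz = pick("toz"), rad = pick("rad"),
               `toz:rad` = pick("toz:rad"),
               residuals = c(a2["Residuals", "Sum Sq"],
                             a2["Residuals", "Df"], NA, NA))
  effects <- data.frame(term = rownames(eff), sumsq = eff[, 1],
                        df = eff[, 2], F = eff[, 3], p = eff[, 4],
                        row.names = NULL)
  p_int <- effects$p[effects$term == "toz:rad"]
  structure(list(effects = effects,
                 mode = if (p_int < alpha) "synergistic" else "additive",
                 alpha = alpha),
            class = "anova_synergy")
}

#' @export
print.anova_synergy <- function(x, ...) {
  print(x$effects, digits = 4)
  cat(sprintf("interaction mode at alpha=%.2g: %s\n", x$alpha, x$mode))
  invisible(x)
}

#' Tukey HSD comparisons among the eight cell means
#'
#' All pairwise comparisons among the design cells using the studentized
#' range distribution with the cell-model error mean square (identical to
#' the full factorial ANOVA's error term).
#'
#' @param tab A single-metric [metric_table()].
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(tab, alpha = 0.05) {
  tab <- one_metric(as.data.frame(tab))
  cell <- factor(paste0("T", tab$toz_level, ".R", tab$rad_level))
  if (nlevels(cell) < 2) stop("Tukey comparisons need at least 2 groups")
  fit <- aov(tab$value ~ cell)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$cell
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha, row.names = NULL)
}

#' Pooled-variance Student's t-test for comparator groups
#'
#' @param a,b Numeric samples (each of size at least 2).
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
comparator_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) stop("zero pooled variance: samples are constant")
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

inverse_transform <- function(x, record) {
  switch(record$transform,
         none = x,
         sqrt = x^2,
         log = exp(x) - record$offset)
}

#' Full synergy report over the five behavioural metrics
#'
#' Per metric: homoscedasticity check with Box-Cox-guided transformation
#' ([check_and_transform()]), two-way ANOVA with the synergy criterion
#' ([two_way_anova()]) and Tukey comparisons among the eight cell means
#' ([tukey_hsd()]), all on the transformed scale when a transform was
#' selected (cell means are back-transformed for display only).  When
#' comparator summaries are supplied, Student's t-tests compare the two
#' L-Dopa regimens and the combination cell against the full L-Dopa
#' regimen, per metric.
#'
#' @param tab A [metric_table()] containing all five metrics.
#' @param comparators Optional data frame with columns `comparator`,
#'   `metric`, `value` for the comparator-group animals.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `synergy_report`.
#' @export
synergy_report <- function(tab, comparators = NULL, alpha = 0.05) {
  tab <- as.data.frame(tab)
  missing <- setdiff(METRICS, unique(tab$metric))
  if (length(missing))
    stop("metric table is missing: ", paste(missing, collapse = ", "))
  per_metric <- list()
  for (m in METRICS) {
    sub <- tab[tab$metric == m, ]
    res <- tryCatch({
      tr <- check_and_transform(sub, alpha = alpha)
      an <- two_way_anova(tr$table, alpha = alpha)
      tk <- tukey_hsd(tr$table, alpha = alpha)
      cm <- aggregate(value ~ toz_level + rad_level, tr$table, mean)
      cm$display_mean <- inverse_transform(cm$value, tr$record)
      list(transform = tr$record, anova = an, tukey = tk, cell_means = cm)
    }, error = function(e)
      stop("metric '", m, "': ", conditionMessage(e), call. = FALSE))
    per_metric[[m]] <- res
  }

  ttests <- NULL
  if (!is.null(comparators)) {
    rows <- list()
    for (m in METRICS) {
      ben <- comparators$value[comparators$comparator == "ldopa_benserazide" &
                                 comparators$metric == m]
      l25 <- comparators$value[comparators$comparator == "ldopa_25" &
                                 comparators$metric == m]
      combo <- tab$value[tab$metric == m & tab$toz_level == 30 &
                           tab$rad_level == 3]
      if (length(ben) >= 2 && length(l25) >= 2) {
        tt <- comparator_ttest(ben, l25)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, comparison = "ldopa_benserazide vs ldopa_25",
          t = tt$t, df = tt$df, p = tt$p)
      }
      if (length(ben) >= 2 && length(combo) >= 2) {
        tt <- comparator_ttest(combo, ben)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, comparison = "toz30_rad3 vs ldopa_benserazide",
          t = tt$t, df = tt$df, p = tt$p)
      }
    }
    if (length(rows)) ttests <- do.call(rbind, rows)
  }
  structure(list(metrics = per_metric, ttests = ttests, alpha = alpha),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("Synergy report (alpha =", x$alpha, ")\n")
  for (m in names(x$metrics)) {
    pm <- x$metrics[[m]]
    eff <- pm$anova$effects
    int <- eff[eff$term == "toz:rad", ]
    cat(sprintf(
      "  %-20s transform=%-5s  interaction F(%d,%d)=%.2f p=%.4g  -> %s\n",
      m, pm$transform$transform, int$df,
      eff$df[eff$term == "residuals"], int$F, int$p, pm$anova$mode))
  }
  if (!is.null(x$ttests)) {
    cat("Comparator t-tests:\n")
    for (i in seq_len(nrow(x$ttests)))
      cat(sprintf("  %-20s %s: t=%.2f df=%d p=%.4g\n",
                  x$ttests$metric[i], x$ttests$comparison[i],
                  x$ttests$t[i], x$ttests$df[i], x$ttests$p[i]))
  }
  invisible(x)
}

#' Write a synergy report as delimited text plus a human-readable summary
#'
#' @param report A [synergy_report()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_synergy_report <- function(report, dir) {
  stopifnot(inherits(report, "synergy_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anova_rows <- list(); tukey_rows <- list(); tr_rows <- list()
  for (m in names(report$metrics)) {
    pm <- report$metrics[[m]]
    eff <- pm$anova$effects
    eff$metric <- m; eff$mode <- pm$anova$mode
    anova_rows[[m]] <- eff
    tk <- pm$tukey; tk$metric <- m
    tukey_rows[[m]] <- tk
    tr_rows[[m]] <- data.frame(metric = m,
                               transform = pm$transform$transform,
                               levene_stat = pm$transform$levene_stat,
                               levene_p = pm$transform$levene_p,
                               boxcox_lambda = pm$transform$lambda,
                               offset = pm$transform$offset)
  }
  paths <- c(anova = file.path(dir, "report_anova.csv"),
             tukey = file.path(dir, "report_tukey.csv"),
             transforms = file.path(dir, "report_transforms.csv"),
             text = file.path(dir, "report.txt"))
  write.csv(do.call(rbind, anova_rows), paths["anova"], row.names = FALSE)
  write.csv(do.call(rbind, tukey_rows), paths["tukey"], row.names = FALSE)
  write.csv(do.call(rbind, tr_rows), paths["transforms"], row.names = FALSE)
  if (!is.null(report$ttests)) {
    paths["ttests"] <- file.path(dir, "report_ttests.csv")
    write.csv(report$ttests, paths["ttests"], row.names = FALSE)
  }
  con <- file(paths["text"], "w")
  sink(con); print(report); sink()
  close(con)
  invisible(paths)
}
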