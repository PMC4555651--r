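#' Score every animal of a cohort
#'
#' Applies [score_animal()] to each trajectory, excluding animals that fail
#' QC with a logged reason.  Aborts when more than `max_cell_failure` of
#' any design cell is lost, since the factorial analysis would no longer be
#' interpretable.
#'
#' @param trajectories Named list of [trajectory()] objects (names =
#'   animal ids).
#' @param cohort A `cohort_table`.
#' @param turn,posture,gyr Metric parameter sets.
#' @param qc_limit Invalid-frame ceiling per session (default 0.1).
#' @param max_cell_failure Abort when more than this fraction of a cell
#'   fails QC (default 0.2).
#' @return Data frame of behaviour summaries (one row per scored animal).
#' @export
score_cohort <- function(trajectories, cohort, turn = turn_params(),
                         posture = posture_params(),
                         gyr = gyration_params(observation = NA),
                         qc_limit = 0.1, max_cell_failure = 0.2) {
  res <- list(); failed <- character(0)
  for (id in cohort$animal_id) {
    traj <- trajectories[[id]]
    if (is.null(traj)) stop("no trajectory supplied for animal '", id, "'")
    out <- tryCatch(score_animal(traj, turn, posture, gyr, qc_limit),
                    error = function(e) e)
    if (inherits(out, "error")) {
      message("QC exclusion of '", id, "': ", conditionMessage(out))
      failed <- c(failed, id)
    } else res[[id]] <- out
  }
  cells <- paste(cohort$toz_dose, cohort$rad_dose, cohort$comparator)
  for (cell in unique(cells)) {
    ids <- cohort$animal_id[cells == cell]
    frac <- mean(ids %in% failed)
    if (frac > max_cell_failure)
      stop(sprintf("aborting: %.0f%% of cell '%s' failed QC (limit %.0f%%)",
                   100 * frac, cell, 100 * max_cell_failure))
  }
  if (length(res) == 0L) stop("no animal passed QC")
  do.call(rbind, res)
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort from `spec`) or
#'   `"ingest"` (read a manifest and per-animal trajectory CSVs).
#' @param out_dir Output directory for all artifacts.
#' @param spec A [cohort_spec()] (simulate mode).
#' @param manifest Path to the cohort manifest CSV (ingest mode).
#' @param trajectory_dir Directory holding `<animal_id>.csv` trajectory
#'   exports (ingest mode).
#' @param arena An [arena_spec()].
#' @param turn,posture,gyr Metric parameter sets.
#' @param alpha Significance level for the statistics (default 0.05).
#' @param seed Master seed (simulate mode; overrides `spec$seed`).
#' @param write_trajectories Also write every simulated session as a
#'   canonical CSV (simulate mode; default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"), out_dir,
                       spec = NULL, manifest = NULL, trajectory_dir = NULL,
                       arena = arena_spec(), turn = turn_params(),
                       posture = posture_params(),
                       gyr = gyration_params(observation = NA),
                       alpha = 0.05, seed = NULL,
                       write_trajectories = FALSE) {
  mode <- match.arg(mode)
  if (mode == "simulate" && !inherits(spec, "cohort_spec"))
    stop("simulate mode needs a cohort_spec")
  if (mode == "ingest") {
    if (is.null(manifest) || !file.exists(manifest))
      stop("ingest mode needs an existing manifest path")
    if (is.null(trajectory_dir) || !dir.exists(trajectory_dir))
      stop("ingest mode needs an existing trajectory_dir")
  }
  structure(list(mode = mode, out_dir = out_dir, spec = spec,
                 manifest = manifest, trajectory_dir = trajectory_dir,
                 arena = arena, turn = turn, posture = posture, gyr = gyr,
                 alpha = alpha, seed = seed,
                 write_trajectories = write_trajectories),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates or ingests a cohort, scores every animal, runs the synergy
#' statistics and writes all artifacts under `config$out_dir`:
#' `summaries.csv`, the report files of [write_synergy_report()], and
#' `run_manifest.yaml` (config echo, package version and seed), which is
#' sufficient to reproduce the run exactly.  Runs are deterministic for a
#' fixed config and seed.
#'
#' @param config A [run_config()].
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "simulate") {
    spec <- config$spec
    if (!is.null(config$seed)) spec$seed <- config$seed
    sim <- simulate_cohort(spec)
    cohort <- sim$cohort; trajs <- sim$trajectories
    if (isTRUE(config$write_trajectories)) {
      tdir <- file.path(config$out_dir, "trajectories")
      dir.create(tdir, showWarnings = FALSE)
      for (id in names(trajs))
        write_trajectory(trajs[[id]], file.path(tdir, paste0(id, ".csv")))
    }
  } else {
    cohort <- read_cohort(config$manifest)
    trajs <- list()
    for (id in cohort$animal_id) {
      f <- file.path(config$trajectory_dir, paste0(id, ".csv"))
      if (!file.exists(f))
        stop("missing trajectory file for animal '", id, "': ", f)
      trajs[[id]] <- read_trajectory(f, arena = config$arena,
                                     animal_id = id)
    }
  }

  summaries <- score_cohort(trajs, cohort, config$turn, config$posture,
                            config$gyr)
  sum_path <- file.path(config$out_dir, "summaries.csv")
  write_summaries(summaries, sum_path)

  tab <- metric_table(summaries, cohort)
  comp <- NULL
  comp_ids <- cohort$animal_id[cohort$comparator != "none"]
  if (length(comp_ids)) {
    cs <- merge(cohort[cohort$comparator != "none",
                       c("animal_id", "comparator")],
                summaries, by = "animal_id")
    comp <- do.call(rbind, lapply(METRICS, function(m)
      data.frame(comparator = cs$comparator, metric = m, value = cs[[m]])))
  }
  report <- synergy_report(tab, comparators = comp, alpha = config$alpha)
  paths <- write_synergy_report(report, config$out_dir)

  manifest <- list(
    package = "ratfield",
    version = as.character(packageVersion("ratfield")),
    mode = config$mode,
    seed = if (config$mode == "simulate") {
      if (!is.null(config$seed)) config$seed else config$spec$seed
    },
    alpha = config$alpha,
    arena = config$arena[c("width", "height", "origin", "view")],
    turn = unclass(config$turn), posture = unclass(config$posture),
    gyration = unclass(config$gyr),
    n_animals_scored = nrow(summaries))
  man_path <- file.path(config$out_dir, "run_manifest.yaml")
  writeLines(yaml::as.yaml(manifest), man_path)

  invisible(c(summaries = sum_path, paths, manifest = man_path))
}
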