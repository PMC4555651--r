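TRAJ_HEADER <- c("time_s", "nose_x", "nose_y", "centre_x", "centre_y",
                 "tail_x", "tail_y")

SUMMARY_HEADER <- c("animal_id", "distance_cm", "ipsi_turns", "contra_turns",
                    "stretched_time_s", "space_occupancy_cm",
                    "qc_invalid_fraction")

#' Read a tracked-trajectory export
#'
#' Reads the canonical comma-delimited tracking export (header
#' `time_s,nose_x,nose_y,centre_x,centre_y,tail_x,tail_y`, coordinates in
#' cm).  Frames with any missing or non-numeric coordinate, or with a point
#' outside the arena box plus `margin`, are flagged invalid.  Runs of up to
#' `max_gap` consecutive invalid frames that are bracketed by valid frames
#' are linearly interpolated (and flagged `interpolated`); longer gaps stay
#' invalid and are excluded from every metric accumulation.
#'
#' @param path Path to the CSV export.
#' @param arena An [arena_spec()].
#' @param rate Sampling rate in Hz (default 25).
#' @param max_gap Longest interpolatable gap, in frames (default 12, i.e.
#'   roughly 0.5 s at 25 Hz).
#' @param margin Tracker-overshoot margin in cm (default 0.5).
#' @param animal_id Identifier; defaults to the file name without extension.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, arena = arena_spec(), rate = 25,
                            max_gap = 12, margin = 0.5,
                            animal_id = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (!identical(names(raw), TRAJ_HEADER))
    stop("bad trajectory header in ", path, ": expected ",
         paste(TRAJ_HEADER, collapse = ","))
  if (nrow(raw) == 0L) stop("empty trajectory file: ", path)

  num <- vapply(raw, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(raw)))
  num <- as.data.frame(matrix(num, nrow = nrow(raw),
                              dimnames = list(NULL, TRAJ_HEADER)))
  if (anyNA(num$time_s) || any(diff(num$time_s) <= 0))
    stop("timestamps missing or not strictly increasing in ", path)

  frames <- data.frame(t = num$time_s,
                       nose_x = num$nose_x, nose_y = num$nose_y,
                       centre_x = num$centre_x, centre_y = num$centre_y,
                       tail_x = num$tail_x, tail_y = num$tail_y,
                       interpolated = FALSE)
  if (is.null(animal_id))
    animal_id <- tools::file_path_sans_ext(basename(path))

  traj <- trajectory(frames, rate = rate, animal_id = animal_id,
                     arena = arena, margin = margin)
  interpolate_gaps(traj, max_gap = max_gap, margin = margin)
}

# Linear interpolation of short invalid runs bracketed by valid frames.
interpolate_gaps <- function(traj, max_gap = 12, margin = 0.5) {
  fr <- traj$frames
  bad <- which(!fr$valid)
  if (length(bad) == 0L) return(traj)
  runs <- split(bad, cumsum(c(1L, diff(bad) != 1L)))
  cols <- c("nose_x", "nose_y", "centre_x", "centre_y", "tail_x", "tail_y")
  for (run in runs) {
    lo <- min(run) - 1L; hi <- max(run) + 1L
    if (length(run) > max_gap || lo < 1L || hi > nrow(fr)) next
    if (!fr$valid[lo] || !fr$valid[hi]) next
    w <- (fr$t[run] - fr$t[lo]) / (fr$t[hi] - fr$t[lo])
    for (cc in cols)
      fr[run, cc] <- (1 - w) * fr[lo, cc] + w * fr[hi, cc]
    fr$valid[run] <- TRUE
    fr$interpolated[run] <- TRUE
  }
  trajectory(fr, rate = traj$rate, animal_id = traj$animal_id,
             arena = traj$arena, margin = margin)
}

#' Write a trajectory in the canonical export dialect
#'
#' @param traj A [trajectory()].  Invalid frames are written with empty
#'   coordinate cells so the file round-trips through [read_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  out <- data.frame(time_s = fmt(fr$t),
                    nose_x = fmt(fr$nose_x), nose_y = fmt(fr$nose_y),
                    centre_x = fmt(fr$centre_x), centre_y = fmt(fr$centre_y),
                    tail_x = fmt(fr$tail_x), tail_y = fmt(fr$tail_y))
  out[!fr$valid, -1] <- ""
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write trajectory to ", path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest assigns each animal either to one cell of the 2 x 4
#' factorial design (Tozadenant dose 0/30 mg/kg by Radiprodil dose
#' 0/1/2/3 mg/kg) or to one of the two L-Dopa comparator groups.  Factorial
#' cells and comparator groups are disjoint; the lesion side (a study
#' constant, right) may be supplied per row or defaults to `"right"`.
#'
#' @param path CSV with columns `animal_id`, `group_label`, `toz_dose`,
#'   `rad_dose`, `comparator` (and optionally `lesion_side`).
#' @param n_expected Expected animals per factorial cell; imbalance is a
#'   warning, not an error (default 8).
#' @return A data frame of class `cohort_table` with a `cell_counts`
#'   attribute.
#' @export
read_cohort <- function(path, n_expected = 8) {
  if (!file.exists(path)) stop("cohort manifest not found: ", path)
  tab <- read.csv(path, check.names = FALSE, strip.white = TRUE,
                  colClasses = "character")
  need <- c("animal_id", "group_label", "toz_dose", "rad_dose", "comparator")
  if (!all(need %in% names(tab)))
    stop("cohort manifest must contain columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty cohort manifest: ", path)
  tab$toz_dose <- suppressWarnings(as.numeric(tab$toz_dose))
  tab$rad_dose <- suppressWarnings(as.numeric(tab$rad_dose))
  if (is.null(tab$lesion_side)) tab$lesion_side <- "right"
  cohort_table(tab, n_expected = n_expected)
}

#' Validate a cohort table
#'
#' @param tab Data frame with the manifest columns (see [read_cohort()]).
#' @param n_expected Expected per-cell size for the balance check.
#' @return The validated `cohort_table`.
#' @export
cohort_table <- function(tab, n_expected = 8) {
  tab <- as.data.frame(tab)
  dup <- tab$animal_id[duplicated(tab$animal_id)]
  if (length(dup))
    stop("duplicate animal_id in cohort: ", paste(unique(dup), collapse = ", "))
  bad_tz <- !(tab$toz_dose %in% c(0, 30))
  bad_rd <- !(tab$rad_dose %in% c(0, 1, 2, 3))
  if (any(bad_tz | bad_rd, na.rm = TRUE) || anyNA(tab$toz_dose) || anyNA(tab$rad_dose)) {
    row <- which(bad_tz | bad_rd | is.na(tab$toz_dose) | is.na(tab$rad_dose))[1]
    stop(sprintf(
      "dose outside the design levels for animal '%s' (row %d): toz=%s, rad=%s",
      tab$animal_id[row], row, tab$toz_dose[row], tab$rad_dose[row]))
  }
  if (!all(tab$comparator %in% c("none", "ldopa_benserazide", "ldopa_25")))
    stop("comparator must be one of none, ldopa_benserazide, ldopa_25")
  if (!all(tab$lesion_side %in% c("left", "right")))
    stop("lesion_side must be 'left' or 'right'")
  comp <- tab$comparator != "none"
  if (any(comp & (tab$toz_dose != 0 | tab$rad_dose != 0)))
    stop("comparator animals cannot also carry factorial doses")

  fac <- tab[!comp, ]
  counts <- table(toz = fac$toz_dose, rad = fac$rad_dose)
  if (length(counts) && any(counts != n_expected))
    warning(sprintf(
      "unbalanced factorial design: cell sizes %s (expected %d per cell)",
      paste(as.vector(counts), collapse = "/"), n_expected))
  structure(tab, class = c("cohort_table", "data.frame"),
            cell_counts = counts)
}

#' Write per-animal behaviour summaries
#'
#' One row per animal with the five behavioural metrics plus the QC
#' invalid-frame fraction, at full float precision so the file round-trips
#' exactly through [read_summaries()].  `NaN` metrics (failed QC) are
#' written as empty cells and re-read as missing.
#'
#' @param summaries A data frame as returned by rbinding [score_animal()]
#'   results (class `behaviour_summary`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0L) stop("no summaries to write")
  if (!all(SUMMARY_HEADER %in% names(summaries)))
    stop("summaries must contain columns: ",
         paste(SUMMARY_HEADER, collapse = ", "))
  out <- summaries[, SUMMARY_HEADER]
  for (cc in SUMMARY_HEADER[-1]) {
    v <- out[[cc]]
    s <- formatC(v, digits = 17, format = "g")
    s[!is.finite(v)] <- ""
    out[[cc]] <- s
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write summaries to ", path)
  invisible(path)
}

#' Read a behaviour-summary table written by [write_summaries()]
#'
#' @param path CSV path.
#' @return Data frame with the summary columns; empty cells become `NA`.
#' @export
read_summaries <- function(path) {
  tab <- read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!all(SUMMARY_HEADER %in% names(tab)))
    stop("not a behaviour-summary file: ", path)
  for (cc in SUMMARY_HEADER[-1]) tab[[cc]] <- as.numeric(tab[[cc]])
  tab
}
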