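# Canonical trial-level data model for the 2 x 2 x 7 TOJ design.

#' Design constants of the TOJ experiment
#'
#' The analysis assumes a fixed factorial trial design: two motion types
#' (radial, rotational) crossed with two initial-direction conditions (same,
#' opposite) and seven signed stimulus-onset asynchronies, each combination
#' repeated 20 times across five analysis blocks (plus one practice block,
#' `block == 0`). Negative asynchronies mean the left stimulus lagged (the
#' right side changed direction first); positive asynchronies mean the left
#' side led.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{asynchronies_ms}{the seven nominal signed asynchronies, ms}
#'   \item{motion_types}{`"radial"`, `"rotational"`}
#'   \item{initial_directions}{`"same"`, `"opposite"`}
#'   \item{groups}{`"percussion"`, `"brass"`, `"color_guard"`}
#'   \item{reps_per_cell}{analysis repetitions per design cell (20)}
#'   \item{n_analysis_blocks}{number of analysis blocks (5)}
#'   \item{trials_per_block}{trials per block (112)}
#'   \item{analysis_trials}{analysis trials per participant (560)}
#'   \item{nonzero_analysis_trials}{nonzero-asynchrony analysis trials (480)}
#' }
#' @export
toj_design <- list(
  asynchronies_ms      = c(-200, -133, -67, 0, 67, 133, 200),
  motion_types         = c("radial", "rotational"),
  initial_directions   = c("same", "opposite"),
  groups               = c("percussion", "brass", "color_guard"),
  reps_per_cell        = 20L,
  n_analysis_blocks    = 5L,
  trials_per_block     = 112L,
  analysis_trials      = 560L,
  nonzero_analysis_trials = 480L
)

toj_trial_columns <- c(
  "participant_id", "group", "motion_type", "initial_directions",
  "asynchrony_ms", "response", "designated_correct", "rt_ms", "block"
)

#' Restrict a trial table to analysis blocks
#'
#' Practice trials (`block == 0`) are retained on ingest so response-bias
#' checks remain possible, but every statistic in the pipeline is computed on
#' the five post-practice blocks only.
#'
#' @param trials a trial tibble as returned by [read_trials()] or
#'   [simulate_trials()].
#' @return the subset of `trials` with `block > 0`.
#' @export
analysis_trials <- function(trials) {
  dplyr::filter(trials, .data$block > 0L)
}

# Snap frame-quantized asynchronies (e.g. 66.67, 133.33 at 60 Hz) to the
# nominal printed values; anything more than 1 ms from a nominal value is
# left untouched so validation can flag it.
normalize_asynchrony <- function(x) {
  nominal <- toj_design$asynchronies_ms
  idx <- vapply(x, function(v) {
    d <- abs(v - nominal)
    if (min(d) <= 1) which.min(d) else NA_integer_
  }, integer(1))
  ifelse(is.na(idx), x, nominal[idx])
}

#' Validate a trial-level TOJ table
#'
#' Checks the factorial trial structure the downstream statistics assume:
#' required columns, legal factor levels, nominal asynchronies (within a
#' +/- 1 ms frame-quantization tolerance, normalized on the way in), positive
#' reaction times, the sign rule linking `designated_correct` to the response
#' for nonzero asynchronies, a single group per participant, and exactly 20
#' analysis trials in each of the 28 design cells per participant.
#'
#' @param trials a data frame of trials with the columns named in the package
#'   CSV contract (see [read_trials()]).
#' @param check_counts if `FALSE`, skip the 20-per-cell balance check
#'   (useful for deliberately truncated designs).
#' @return the validated tibble, with asynchronies normalized to nominal
#'   values, invisibly classed as `toj_trials`.
#' @export
validate_trials <- function(trials, check_counts = TRUE) {
  trials <- tibble::as_tibble(trials)

  missing <- setdiff(toj_trial_columns, names(trials))
  extra   <- setdiff(names(trials), toj_trial_columns)
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra) > 0) {
    stop("trial table has unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  trials <- trials[, toj_trial_columns]

  check_levels <- function(col, levels) {
    bad <- setdiff(unique(trials[[col]]), levels)
    if (length(bad) > 0) {
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_levels("group", toj_design$groups)
  check_levels("motion_type", toj_design$motion_types)
  check_levels("initial_directions", toj_design$initial_directions)
  check_levels("response", c("left_first", "right_first"))

  trials$asynchrony_ms <- normalize_asynchrony(trials$asynchrony_ms)
  bad_x <- !trials$asynchrony_ms %in% toj_design$asynchronies_ms
  if (any(bad_x)) {
    stop("asynchrony_ms outside the nominal set in row(s): ",
         paste(utils::head(which(bad_x), 10), collapse = ", "), call. = FALSE)
  }

  if (any(!is.finite(trials$rt_ms) | trials$rt_ms <= 0)) {
    stop("rt_ms must be positive and finite; offending row(s): ",
         paste(utils::head(which(!is.finite(trials$rt_ms) | trials$rt_ms <= 0), 10),
               collapse = ", "), call. = FALSE)
  }
  if (!is.logical(trials$designated_correct)) {
    stop("designated_correct must be logical", call. = FALSE)
  }
  if (any(trials$block < 0) || any(trials$block != floor(trials$block))) {
    stop("block must be a non-negative integer", call. = FALSE)
  }
  trials$block <- as.integer(trials$block)

  # sign rule: for X != 0, the trial is scored correct iff the response was
  # left_first exactly when the left side led (X > 0)
  nz <- trials$asynchrony_ms != 0
  expected <- (trials$response == "left_first") == (trials$asynchrony_ms > 0)
  bad_sign <- nz & (trials$designated_correct != expected)
  if (any(bad_sign)) {
    stop("designated_correct disagrees with the asynchrony sign rule in row(s): ",
         paste(utils::head(which(bad_sign), 10), collapse = ", "), call. = FALSE)
  }

  multi_group <- trials |>
    dplyr::distinct(.data$participant_id, .data$group) |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi_group) > 0) {
    stop("participant(s) mapped to more than one group: ",
         paste(multi_group$participant_id, collapse = ", "), call. = FALSE)
  }

  if (check_counts) {
    counts <- trials |>
      analysis_trials() |>
      dplyr::count(.data$participant_id, .data$motion_type,
                   .data$initial_directions, .data$asynchrony_ms)
    bad <- dplyr::filter(counts, .data$n != toj_design$reps_per_cell)
    n_cells <- length(toj_design$motion_types) *
      length(toj_design$initial_directions) *
      length(toj_design$asynchronies_ms)
    full <- trials |>
      analysis_trials() |>
      dplyr::distinct(.data$participant_id, .data$motion_type,
                      .data$initial_directions, .data$asynchrony_ms) |>
      dplyr::count(.data$participant_id) |>
      dplyr::filter(.data$n != n_cells)
    if (nrow(bad) > 0 || nrow(full) > 0) {
      describe <- function(df) {
        paste(sprintf("%s/%s/%s/%+d ms (n=%d)", df$participant_id,
                      df$motion_type, df$initial_directions,
                      df$asynchrony_ms, df$n), collapse = "; ")
      }
      msg <- if (nrow(bad) > 0) describe(bad) else
        paste("missing cells for participant(s):",
              paste(full$participant_id, collapse = ", "))
      stop("unbalanced design cells: ", msg, call. = FALSE)
    }
  }

  class(trials) <- unique(c("toj_trials", class(trials)))
  invisible(trials)
}

#' Read a trial-level TOJ table from CSV
#'
#' The package's canonical format is a UTF-8 comma-separated file with header
#' `participant_id, group, motion_type, initial_directions, asynchrony_ms,
#' response, designated_correct, rt_ms, block` and `.`-decimal numbers.
#' Frame-quantized asynchronies are normalized to the nominal values on
#' ingest. Practice trials (`block == 0`) are retained; use
#' [analysis_trials()] to drop them.
#'
#' @param path path to a CSV file.
#' @param check_counts passed to [validate_trials()].
#' @return a validated `toj_trials` tibble with a `provenance` attribute
#'   recording the source file.
#' @export
read_trials <- function(path, check_counts = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id     = readr::col_character(),
      group              = readr::col_character(),
      motion_type        = readr::col_character(),
      initial_directions = readr::col_character(),
      asynchrony_ms      = readr::col_double(),
      response           = readr::col_character(),
      designated_correct = readr::col_logical(),
      rt_ms              = readr::col_double(),
      block              = readr::col_integer()
    )
  )
  trials <- validate_trials(trials, check_counts = check_counts)
  attr(trials, "provenance") <- list(source = path)
  trials
}

#' Write a trial-level TOJ table to CSV
#'
#' Rows are sorted deterministically (participant, block, then input order
#' within block) and columns emitted in the canonical order, so
#' write -> read -> write round-trips byte-identically.
#'
#' @param trials a trial tibble (validated or validatable).
#' @param path output file path.
#' @param check_counts passed to [validate_trials()].
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, check_counts = TRUE) {
  trials <- validate_trials(trials, check_counts = check_counts)
  trials <- dplyr::arrange(trials, .data$participant_id, .data$block)
  out <- trials[, toj_trial_columns]
  class(out) <- class(tibble::tibble())
  readr::write_csv(out, path)
  invisible(path)
}
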