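# Signal-detection d' for TOJ data, on the half-scaled z convention:
# d' = Z(hits) - Z(false alarms) with the Z distribution's SD set to 0.5,
# so d' = 0.67 corresponds to unbiased 75% correct.

#' Half-scaled normal quantile
#'
#' Returns `0.5 * qnorm(p)`: the quantile of a normal distribution with SD
#' 0.5. This is the z-transform convention under which an unbiased 75%
#' correct observer scores d' = 0.67.
#'
#' @param p proportion(s) strictly inside (0, 1); extreme counts must be
#'   corrected upstream with [correct_extreme()].
#' @return numeric vector of half-scaled z values.
#' @export
z_half <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("p must lie strictly in (0, 1); apply correct_extreme() first",
         call. = FALSE)
  }
  0.5 * qnorm(p)
}

#' Correct extreme hit or false-alarm counts
#'
#' Counts of 0 become 0.5 successes and counts of `n` become `n - 0.5`
#' successes before conversion to a proportion, so the z-transform stays
#' finite; interior counts pass through as `count / n`. The pools the design
#' produces hold 20 (per-asynchrony) or 60 (pooled-sign) trials.
#'
#' @param count integer count(s), `0 <= count <= n`.
#' @param n pool size; 20 or 60 unless `allow_any_n = TRUE`.
#' @param allow_any_n permit pool sizes other than 20/60 (off by default so
#'   partial designs are rejected rather than silently corrected).
#' @return corrected proportion(s) strictly inside (0, 1).
#' @export
correct_extreme <- function(count, n, allow_any_n = FALSE) {
  if (!allow_any_n && !all(n %in% c(20L, 60L))) {
    stop("pool size must be 20 or 60 (set allow_any_n = TRUE to override)",
         call. = FALSE)
  }
  if (any(count < 0 | count > n)) stop("count must lie in [0, n]", call. = FALSE)
  adj <- pmin(pmax(count, 0.5), n - 0.5)
  adj / n
}

#' d' from corrected hit and false-alarm proportions
#'
#' `d' = z_half(hit_prop) - z_half(fa_prop)`. Antisymmetric under swapping
#' hits and false alarms, and zero whenever the two proportions agree.
#'
#' @param hit_prop,fa_prop proportions strictly inside (0, 1).
#' @return d' value(s) on the half-scaled convention.
#' @export
dprime <- function(hit_prop, fa_prop) {
  z_half(hit_prop) - z_half(fa_prop)
}

#' Per-participant d' table (12 per-asynchrony + 4 pooled entries)
#'
#' Hits are "left first" responses when the left stimulus led (positive
#' asynchrony); false alarms are "left first" responses when it lagged
#' (negative asynchrony). For each motion x initial-directions cell, three
#' entries pair the +X and -X trials of each magnitude (20 trials per sign),
#' and a fourth pools all positive (60) against all negative (60) trials.
#' Zero-asynchrony trials never enter d'. Each participant therefore
#' contributes exactly 16 entries.
#'
#' @param trials a validated `toj_trials` tibble (practice trials are
#'   dropped internally).
#' @param participant_id optional character vector restricting the table to
#'   specific participants.
#' @return a tibble with one row per participant x motion x direction x
#'   asynchrony class (`"67"`, `"133"`, `"200"`, `"pooled"`), carrying the
#'   raw counts, corrected proportions, half-scaled z values, and `dprime`.
#' @export
dprime_table <- function(trials, participant_id = NULL) {
  trials <- analysis_trials(trials)
  if (!is.null(participant_id)) {
    trials <- dplyr::filter(trials, .data$participant_id %in% !!participant_id)
    if (nrow(trials) == 0) stop("no trials for requested participant(s)",
                                call. = FALSE)
  }
  nz <- dplyr::filter(trials, .data$asynchrony_ms != 0) |>
    dplyr::mutate(
      magnitude = abs(.data$asynchrony_ms),
      side = ifelse(.data$asynchrony_ms > 0, "pos", "neg"),
      left_first = .data$response == "left_first"
    )

  tally <- function(df, class_label) {
    df |>
      dplyr::group_by(.data$participant_id, .data$group, .data$motion_type,
                      .data$initial_directions, .data$side) |>
      dplyr::summarise(n_left = sum(.data$left_first), n = dplyr::n(),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "side",
                         values_from = c("n_left", "n")) |>
      dplyr::mutate(asynchrony_class = class_label)
  }

  per_x <- nz |>
    dplyr::group_by(.data$magnitude) |>
    dplyr::group_map(~ tally(.x, as.character(.y$magnitude)) ) |>
    dplyr::bind_rows()
  pooled <- tally(nz, "pooled")
  tab <- dplyr::bind_rows(per_x, pooled)

  if (any(is.na(tab$n_pos)) || any(is.na(tab$n_neg))) {
    stop("participant is missing trials on one asynchrony sign", call. = FALSE)
  }
  bad <- tab$n_pos != ifelse(tab$asynchrony_class == "pooled", 60L, 20L) |
         tab$n_neg != ifelse(tab$asynchrony_class == "pooled", 60L, 20L)
  if (any(bad)) {
    stop("d' pools must hold 20 (per-asynchrony) or 60 (pooled) trials; ",
         "offending participant(s): ",
         paste(unique(tab$participant_id[bad]), collapse = ", "), call. = FALSE)
  }

  tab |>
    dplyr::mutate(
      hit_prop = correct_extreme(.data$n_left_pos, .data$n_pos),
      fa_prop  = correct_extreme(.data$n_left_neg, .data$n_neg),
      z_hit = z_half(.data$hit_prop),
      z_fa  = z_half(.data$fa_prop),
      dprime = .data$z_hit - .data$z_fa,
      asynchrony_class = factor(.data$asynchrony_class,
                                levels = c("67", "133", "200", "pooled"))
    ) |>
    dplyr::rename(n_hit = "n_left_pos", n_fa = "n_left_neg") |>
    dplyr::select("participant_id", "group", "motion_type",
                  "initial_directions", "asynchrony_class", "n_hit", "n_fa",
                  "hit_prop", "fa_prop", "z_hit", "z_fa", "dprime") |>
    dplyr::arrange(.data$participant_id, .data$motion_type,
                   .data$initial_directions, .data$asynchrony_class)
}
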