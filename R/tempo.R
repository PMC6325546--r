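# Deterministic conversions between musical tempo subdivisions, temporal
# frequencies, TOJ thresholds, and color-guard rotation angles. All values
# are exact internally; rounding to printed precision belongs to the
# reporting layer (see tempo_grid()).

#' Tempo context for musical and angular conversions
#'
#' @param tempo tempo in beats per minute (> 0).
#' @param subdivision notes per beat: 1 (quarter), 2 (8th), 4 (16th), or 8
#'   (32nd).
#' @param rotation_rate rotation speed in degrees per ms for the angular
#'   mapping; the default 0.72 corresponds to a full 360 degree rotation
#'   every 500 ms (a 120 beats/min marching tempo).
#' @return a `toj_tempo_ctx` list.
#' @export
tempo_context <- function(tempo, subdivision = 1, rotation_rate = 0.72) {
  if (tempo <= 0) stop("tempo must be positive", call. = FALSE)
  if (!subdivision %in% c(1, 2, 4, 8)) {
    stop("subdivision must be one of 1, 2, 4, 8", call. = FALSE)
  }
  if (rotation_rate <= 0) stop("rotation_rate must be positive", call. = FALSE)
  structure(list(tempo = tempo, subdivision = subdivision,
                 rotation_rate = rotation_rate), class = "toj_tempo_ctx")
}

#' Duration of one note at a tempo context, in ms
#'
#' `60000 / tempo / subdivision` (exact; e.g. a 32nd note at 180 beats/min
#' lasts 41.67 ms to two decimals).
#'
#' @param ctx a [tempo_context()].
#' @return duration in ms.
#' @export
note_duration_ms <- function(ctx) {
  60000 / ctx$tempo / ctx$subdivision
}

#' Temporal frequency of a note stream, in Hz
#'
#' The reciprocal of [note_duration_ms()] in seconds:
#' `tempo * subdivision / 60`.
#'
#' @param ctx a [tempo_context()].
#' @return frequency in Hz.
#' @export
note_frequency_hz <- function(ctx) {
  ctx$tempo * ctx$subdivision / 60
}

#' Convert a TOJ threshold (ms) to a temporal frequency (Hz)
#'
#' `1000 / threshold_ms`; a 29 ms threshold corresponds to 34.48 Hz.
#'
#' @param threshold_ms threshold in ms (> 0).
#' @return frequency in Hz.
#' @export
threshold_to_hz <- function(threshold_ms) {
  if (any(threshold_ms <= 0)) stop("threshold must be positive", call. = FALSE)
  1000 / threshold_ms
}

#' Angular mismatch created by a temporal asynchrony
#'
#' At rotation rate `r` degrees/ms, an asynchrony of `t` ms between two
#' rotating objects corresponds to an angular mismatch of `r * t` degrees
#' (200 ms at 0.72 degrees/ms gives exactly 144 degrees). Values are
#' returned unrounded; note that at 133 ms the exact value is 95.76 degrees.
#'
#' @param asynchrony_ms non-negative asynchrony in ms.
#' @param ctx a [tempo_context()] supplying `rotation_rate`.
#' @return angular mismatch in degrees.
#' @export
angular_mismatch_deg <- function(asynchrony_ms, ctx = tempo_context(120)) {
  if (any(asynchrony_ms < 0)) stop("asynchrony must be >= 0", call. = FALSE)
  asynchrony_ms * ctx$rotation_rate
}

#' Asynchrony at which two rotating objects are in antiphase
#'
#' The inverse of [angular_mismatch_deg()] at 180 degrees:
#' `180 / rotation_rate` ms (250 ms at 0.72 degrees/ms).
#'
#' @param ctx a [tempo_context()].
#' @return asynchrony in ms.
#' @export
antiphase_asynchrony_ms <- function(ctx = tempo_context(120)) {
  180 / ctx$rotation_rate
}

#' Note duration / frequency grid at common drum-corps tempos
#'
#' The quarter- through 32nd-note durations (ms) and temporal frequencies
#' (Hz) at the requested tempos, rounded to two decimals for reporting.
#'
#' @param tempos tempos in beats/min (default the common marching tempos
#'   180 and 120).
#' @return a tibble with one row per tempo x subdivision.
#' @export
tempo_grid <- function(tempos = c(180, 120)) {
  subdivisions <- c(quarter = 1, eighth = 2, sixteenth = 4, thirty_second = 8)
  tidyr::expand_grid(tempo = tempos, note = names(subdivisions)) |>
    dplyr::mutate(
      subdivision = unname(subdivisions[.data$note]),
      duration_ms = round(60000 / .data$tempo / .data$subdivision, 2),
      frequency_hz = round(.data$tempo * .data$subdivision / 60, 2)
    )
}
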