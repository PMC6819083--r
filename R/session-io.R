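#' Read and validate a demodulated photometry session
#'
#' Sessions are plain CSV with header columns `time_s`, `ch490`, `ch405`
#' (comma separator, `.` decimal, UTF-8). Timestamps must be uniformly
#' spaced; the sampling rate is inferred from the median sample spacing.
#'
#' @param path CSV file path.
#' @param rel_tol relative tolerance on sample spacing (default `1e-9`);
#'   files with a larger gap are rejected, naming the first offending index.
#' @return tibble with columns `time_s`, `ch490`, `ch405` (plus any extra
#'   columns present, e.g. `edge`), with the inferred sampling rate in
#'   attribute `"fs"`.
#' @export
read_photometry_session <- function(path, rel_tol = 1e-9) {
  # base read.csv parses doubles with strtod (correctly rounded), so values
  # written with shortest round-trip formatting are reproduced bit-exactly
  df <- as_tibble(utils::read.csv(path))
  check_columns(df, c("time_s", "ch490", "ch405"), sprintf("'%s'", path))
  fs <- check_uniform_time(df$time_s, rel_tol = rel_tol)
  if (!all(is.finite(df$ch490)) || !all(is.finite(df$ch405))) {
    abort(sprintf("'%s' contains non-finite channel values.", path))
  }
  attr(df, "fs") <- fs
  df
}

#' Write a photometry session to CSV
#'
#' Values are written with shortest round-trip formatting so a write/read
#' cycle reproduces the numbers exactly.
#'
#' @param session tibble with columns `time_s`, `ch490`, `ch405`.
#' @param path output CSV path.
#' @return `session`, invisibly.
#' @export
write_photometry_session <- function(session, path) {
  check_columns(session, c("time_s", "ch490", "ch405"), "`session`")
  readr::write_csv(session, path, progress = FALSE)
  invisible(session)
}

#' Default event label vocabulary
#'
#' The labels produced by the trial schedule generator and consumed by the
#' peri-event module. Sessions may declare their own vocabulary; unknown
#' labels are preserved but flagged by [validate_events()].
#'
#' @return character vector of labels.
#' @export
event_vocabulary <- function() {
  c("CS_ON", "CS_OFF", "US_ON", "PUMP", "LIGHT_ON", "TONE_ON", "SHOCK_ON", "TTL")
}

#' Read an event table
#'
#' Events are CSV with header columns `time_s` (seconds, non-decreasing) and
#' `label`. Unparseable times are rejected with their row number;
#' out-of-order rows are rejected.
#'
#' @param path CSV file path.
#' @return tibble with columns `time_s`, `label`.
#' @export
read_events <- function(path) {
  df <- as_tibble(utils::read.csv(path, colClasses = "character"))
  check_columns(df, c("time_s", "label"), sprintf("'%s'", path))
  time_s <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(time_s)) {
    abort(sprintf(
      "'%s' has an unparseable time at row %d.", path, which(is.na(time_s))[1]
    ))
  }
  df$time_s <- time_s
  if (is.unsorted(df$time_s)) {
    bad <- which(diff(df$time_s) < 0)[1] + 1L
    abort(sprintf("'%s' events are out of order at row %d.", path, bad))
  }
  df
}

#' @rdname read_events
#' @param events event tibble with columns `time_s`, `label`.
#' @export
write_events <- function(events, path) {
  check_columns(events, c("time_s", "label"), "`events`")
  readr::write_csv(events, path, progress = FALSE)
  invisible(events)
}

#' Validate event labels against a vocabulary
#'
#' @param events event tibble with columns `time_s`, `label`.
#' @param vocabulary allowed labels (default [event_vocabulary()]).
#' @return a per-label report tibble (`label`, `n`, `known`); unknown labels
#'   are flagged, never dropped.
#' @export
validate_events <- function(events, vocabulary = event_vocabulary()) {
  check_columns(events, c("time_s", "label"), "`events`")
  events |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(known = .data$label %in% vocabulary) |>
    dplyr::arrange(dplyr::desc(.data$known), .data$label)
}

#' Align behavioral event times onto the photometry clock
#'
#' Both clocks record the same synchronization TTL pulse; every behavioral
#' event time is shifted by `ttl_time_photometry_s - ttl_time_behavior_s` so
#' that the photometry clock is canonical. Applying the negated offset
#' restores the original table exactly.
#'
#' @param events event tibble with columns `time_s`, `label` on the
#'   behavioral clock.
#' @param ttl_time_photometry_s TTL pulse time on the photometry clock (s).
#' @param ttl_time_behavior_s the same pulse on the behavioral clock (s).
#' @return the event tibble with `time_s` shifted; ordering is preserved.
#' @examples
#' ev <- tibble::tibble(time_s = 10, label = "CS_ON")
#' align_events(ev, ttl_time_photometry_s = 5, ttl_time_behavior_s = 2)
#' @export
align_events <- function(events, ttl_time_photometry_s, ttl_time_behavior_s) {
  check_columns(events, c("time_s", "label"), "`events`")
  check_scalar_number(ttl_time_photometry_s, "ttl_time_photometry_s")
  check_scalar_number(ttl_time_behavior_s, "ttl_time_behavior_s")
  dplyr::mutate(
    events,
    time_s = .data$time_s + (ttl_time_photometry_s - ttl_time_behavior_s)
  )
}
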