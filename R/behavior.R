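#' Detect lick bouts
#'
#' A bout starts at the first lick of any run in which at least
#' `rate_threshold * window_s` licks fall within a sliding `window_s`-second
#' window (the operational form of a "exceeds five licks/second" rule), and
#' ends when no lick occurs for `gap_s` seconds. Bouts separated by less
#' than `gap_s` are merged, and bouts with fewer than `min_licks` licks are
#' discarded.
#'
#' @param licks data frame with a `time_s` column of sorted lick
#'   timestamps, or a sorted numeric vector.
#' @param rate_threshold bout-qualifying lick rate in licks/s (default 5).
#' @param gap_s silence that terminates a bout, and the minimal separation
#'   between distinct bouts, in seconds (default 3).
#' @param min_licks minimal licks per bout (default 5, consistent with the
#'   rate rule at the 1 s scale).
#' @param window_s width of the sliding rate window in seconds (default 1).
#' @return tibble with one row per bout: `start_s`, `end_s`, `n_licks`,
#'   `peak_rate_licks_per_s` (maximal `window_s` count / `window_s` within
#'   the bout).
#' @examples
#' licks <- c(seq(0, 0.9, by = 0.1), seq(6, 6.9, by = 0.1))
#' detect_lick_bouts(licks)
#' @export
detect_lick_bouts <- function(licks, rate_threshold = 5, gap_s = 3,
                              min_licks = 5, window_s = 1) {
  tt <- if (is.data.frame(licks)) {
    check_columns(licks, "time_s", "`licks`")
    licks$time_s
  } else {
    licks
  }
  if (is.unsorted(tt)) abort("Lick timestamps must be sorted.")
  n <- length(tt)
  empty <- tibble(
    start_s = numeric(), end_s = numeric(),
    n_licks = integer(), peak_rate_licks_per_s = numeric()
  )
  if (n == 0) return(empty)

  need <- ceiling(rate_threshold * window_s)
  # count of licks in [t_i, t_i + window_s) for each lick i
  upper <- findInterval(tt + window_s, tt, left.open = TRUE)
  win_count <- upper - seq_len(n) + 1L
  qualifies <- win_count >= need
  if (!any(qualifies)) return(empty)

  # group licks into runs separated by >= gap_s of silence
  run_id <- cumsum(c(1, as.integer(diff(tt) >= gap_s)))
  bouts <- lapply(split(seq_len(n), run_id), function(idx) {
    q <- idx[qualifies[idx]]
    if (length(q) == 0) return(NULL)
    start_i <- q[1]
    # bout spans from the first qualifying lick to the last lick of the run
    span <- idx[idx >= start_i]
    rates <- win_count[span] / window_s
    tibble(
      start_s = tt[start_i], end_s = tt[span[length(span)]],
      n_licks = length(span), peak_rate_licks_per_s = max(rates)
    )
  })
  bouts <- dplyr::bind_rows(bouts)
  if (nrow(bouts) == 0) return(empty)

  # merge bouts whose silent separation is below gap_s (can arise when the
  # qualifying lick starts mid-run), then apply the size filter
  if (nrow(bouts) > 1) {
    bouts$merge_id <- cumsum(c(1, as.integer(
      bouts$start_s[-1] - bouts$end_s[-nrow(bouts)] >= gap_s
    )))
    bouts <- bouts |>
      dplyr::group_by(.data$merge_id) |>
      dplyr::summarise(
        start_s = min(.data$start_s), end_s = max(.data$end_s),
        n_licks = sum(.data$n_licks),
        peak_rate_licks_per_s = max(.data$peak_rate_licks_per_s),
        .groups = "drop"
      ) |>
      dplyr::select(-"merge_id")
  }
  dplyr::filter(bouts, .data$n_licks >= min_licks)
}

#' Locate the US consumption time from lick bouts
#'
#' Reward consumption often happens after the nominal pump command, so the
#' effective US time of a trial is the start of the first lick bout at or
#' after reward presentation. Trials with no such bout get `NA` (missing is
#' a value, not an error).
#'
#' @param bouts bout tibble from [detect_lick_bouts()].
#' @param reward_time_s reward presentation time(s) in seconds; vectorized
#'   over trials.
#' @return tibble with columns `reward_time_s`, `us_time_s` (`NA` when no
#'   bout follows the reward).
#' @examples
#' b <- tibble::tibble(start_s = c(8, 15), end_s = c(9, 16),
#'                     n_licks = 8L, peak_rate_licks_per_s = 8)
#' us_time_from_licks(b, reward_time_s = 10)
#' @export
us_time_from_licks <- function(bouts, reward_time_s) {
  check_columns(bouts, c("start_s", "end_s"), "`bouts`")
  if (any(!is.finite(reward_time_s))) abort("`reward_time_s` must be finite.")
  us <- vapply(reward_time_s, function(rt) {
    cand <- bouts$start_s[bouts$start_s >= rt]
    if (length(cand) == 0) NA_real_ else min(cand)
  }, numeric(1))
  tibble(reward_time_s = reward_time_s, us_time_s = us)
}

#' Count CS-period and anticipatory licks per trial
#'
#' Licks are attributed to each trial's CS presentation window
#' `[onset, onset + cs_duration_s)` and to the anticipatory window
#' `[onset, onset + us_offset_s)` (CS onset up to, excluding, US delivery).
#'
#' @param licks sorted lick timestamps (vector or data frame with `time_s`).
#' @param schedule trial schedule tibble with columns `trial`, `onset_s`,
#'   `cs_duration_s`, `us_offset_s` (see [simulate_trial_schedule()]).
#' @return tibble with columns `trial`, `cs_licks`, `anticipatory_licks`.
#' @export
count_trial_licks <- function(licks, schedule) {
  tt <- if (is.data.frame(licks)) licks$time_s else licks
  check_columns(schedule, c("trial", "onset_s", "cs_duration_s"), "`schedule`")
  us_off <- if ("us_offset_s" %in% names(schedule)) {
    schedule$us_offset_s
  } else {
    rep(NA_real_, nrow(schedule))
  }
  purrr::pmap_dfr(
    list(schedule$trial, schedule$onset_s, schedule$cs_duration_s, us_off),
    function(trial, onset, cs_dur, us) {
      tibble(
        trial = trial,
        cs_licks = sum(tt >= onset & tt < onset + cs_dur),
        anticipatory_licks = if (is.na(us)) {
          NA_integer_
        } else {
          sum(tt >= onset & tt < onset + us)
        }
      )
    }
  )
}

#' Learning rate: slope of CS licks across trials
#'
#' Ordinary least-squares slope of per-trial CS lick counts against the
#' 1-based trial index, in licks/trial. The same statistic applied to
#' per-session counts gives the across-session learning rate.
#'
#' @param cs_licks data frame with a `cs_licks` column (and optionally
#'   `trial`), or a numeric vector of per-trial counts; needs >= 3 trials.
#' @return one-row tibble: `slope`, `intercept`, `r2`, `n`.
#' @examples
#' learning_rate(seq(0, 18, by = 2))
#' @export
learning_rate <- function(cs_licks) {
  y <- if (is.data.frame(cs_licks)) {
    check_columns(cs_licks, "cs_licks", "`cs_licks`")
    cs_licks$cs_licks
  } else {
    cs_licks
  }
  if (length(y) < 3) abort("`learning_rate()` needs at least 3 trials.")
  feature_trend(tibble(value = as.numeric(y)))
}

#' Freezing acquisition metrics from scored trials
#'
#' From per-trial freezing scores: the acquisition slope (OLS of freezing
#' time against trial over the acquisition trials, default 1-7) and the
#' plateau behavior (mean freezing time and mean latency to freeze over the
#' plateau trials, default 8-15).
#'
#' @param records tibble with columns `trial`, `freeze_time_s` and
#'   optionally `latency_s`.
#' @param acquisition_trials,plateau_trials trial index vectors (defaults
#'   `1:7` and `8:15`); all must be present in `records`.
#' @return one-row tibble: `acquisition_slope`, `mean_freeze_s`,
#'   `mean_latency_s` (`NA` when `latency_s` is absent).
#' @export
freezing_acquisition <- function(records,
                                 acquisition_trials = 1:7,
                                 plateau_trials = 8:15) {
  check_columns(records, c("trial", "freeze_time_s"), "`records`")
  missing <- setdiff(c(acquisition_trials, plateau_trials), records$trial)
  if (length(missing) > 0) {
    abort(sprintf(
      "Too few trials: trial%s %s missing from `records`.",
      if (length(missing) > 1) "s" else "",
      paste(missing, collapse = ", ")
    ))
  }
  acq <- records[records$trial %in% acquisition_trials, ]
  acq <- acq[order(acq$trial), ]
  plat <- records[records$trial %in% plateau_trials, ]
  slope <- feature_trend(
    tibble(value = acq$freeze_time_s, idx = acq$trial),
    value = "value", index = "idx"
  )$slope
  tibble(
    acquisition_slope = slope,
    mean_freeze_s = mean(plat$freeze_time_s),
    mean_latency_s = if ("latency_s" %in% names(plat)) {
      mean(plat$latency_s)
    } else {
      NA_real_
    }
  )
}
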