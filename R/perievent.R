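#' Extract event-aligned trials from a normalized trace
#'
#' Slices the session trace into windows of `pre_s` seconds before to
#' `post_s` seconds after every event carrying `label`. Rows are exact
#' sample slices — no resampling — so every trial has
#' `round((pre_s + post_s) * fs) + 1` samples. Events whose window would
#' extend past the trace are dropped and reported (attribute `"dropped"`),
#' never padded.
#'
#' @param x trace tibble with columns `time_s` and the value column `col`
#'   (default `"z"`), e.g. from [process_session()].
#' @param events event tibble with columns `time_s`, `label`.
#' @param label event label to align to (e.g. `"CS_ON"`).
#' @param pre_s,post_s window extent in seconds before/after the event.
#' @param baseline_s optional per-trial baseline: when given, the mean over
#'   `[-baseline_s, 0)` is subtracted from each trial (default `NULL`, off;
#'   session-level normalization is the norm).
#' @param col trace column name (default `"z"`).
#' @return long tibble of class `"perievent_matrix"` with columns `trial`,
#'   `event_time_s`, `time_rel_s`, `z`; trials are ordered by event time.
#'   Attributes: `"window"` (`c(pre_s, post_s)`), `"label"`, `"fs"`,
#'   `"dropped"` (tibble of dropped events with reasons).
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 30, seed = 1))
#' zdf <- process_session(demodulate_session(sim$raw))
#' ev <- tibble::tibble(time_s = c(10, 20), label = "CS_ON")
#' mat <- extract_perievent(zdf, ev, "CS_ON", pre_s = 2, post_s = 5)
#' @export
extract_perievent <- function(x, events, label, pre_s, post_s,
                              baseline_s = NULL, col = "z") {
  check_columns(x, c("time_s", col), "`x`")
  check_columns(events, c("time_s", "label"), "`events`")
  check_scalar_number(pre_s, "pre_s")
  check_scalar_number(post_s, "post_s")
  fs <- check_uniform_time(x$time_s)
  t0 <- x$time_s[1]
  n <- nrow(x)
  ev_t <- sort(events$time_s[events$label == label])
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  rel <- seq.int(-n_pre, n_post) / fs

  rows <- list()
  dropped <- list()
  trial <- 0L
  for (te in ev_t) {
    i0 <- round((te - t0) * fs) + 1
    if (i0 - n_pre < 1 || i0 + n_post > n) {
      dropped[[length(dropped) + 1L]] <- tibble(
        event_time_s = te,
        reason = sprintf(
          "window [%g, %g] s extends outside the trace", te - pre_s, te + post_s
        )
      )
      next
    }
    trial <- trial + 1L
    zi <- x[[col]][seq.int(i0 - n_pre, i0 + n_post)]
    if (!is.null(baseline_s) && baseline_s > 0) {
      base <- rel >= -baseline_s & rel < 0
      if (any(base)) zi <- zi - mean(zi[base])
    }
    rows[[trial]] <- tibble(
      trial = trial, event_time_s = te, time_rel_s = rel, z = zi
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(
      trial = integer(), event_time_s = numeric(),
      time_rel_s = numeric(), z = numeric()
    )
  }
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else {
    tibble(event_time_s = numeric(), reason = character())
  }
  if (nrow(dropped) > 0) {
    warn(sprintf(
      "%d trial%s dropped (window outside trace); see attr(, \"dropped\").",
      nrow(dropped), if (nrow(dropped) > 1) "s" else ""
    ))
  }
  attr(out, "window") <- c(pre_s = pre_s, post_s = post_s)
  attr(out, "label") <- label
  attr(out, "fs") <- fs
  attr(out, "dropped") <- dropped
  class(out) <- c("perievent_matrix", class(out))
  out
}

#' Feature windows for peri-event trial quantification
#'
#' Default analysis windows, in seconds relative to the aligned (CS) event:
#' CS peak over `[0, 2]` after CS onset; US peak over `[0, 1]` after the US;
#' US anti-peak over `[0.5, 2.5]` after the US; post-US rebound AUC over
#' `[2, 8]` after the US; baseline mean over `[-2, 0]`. These reflect the
#' canonical aversive-US waveform — an initial positive transient, a 1-2 s
#' negative anti-peak, then a broader rebound — and are all configurable.
#'
#' @param us_offset_s US onset relative to the aligned event (default 0:
#'   the matrix is aligned to the US itself; use 7 for a matrix aligned to a
#'   pavlovian CS onset).
#' @param cs_peak,us_peak,us_antipeak,rebound_auc,baseline length-2 windows
#'   in seconds; the three US windows are relative to the US and shifted by
#'   `us_offset_s`.
#' @return named list of windows relative to the aligned event.
#' @export
feature_windows <- function(us_offset_s = 0,
                            cs_peak = c(0, 2),
                            us_peak = c(0, 1),
                            us_antipeak = c(0.5, 2.5),
                            rebound_auc = c(2, 8),
                            baseline = c(-2, 0)) {
  list(
    cs_peak = cs_peak,
    us_peak = us_offset_s + us_peak,
    us_antipeak = us_offset_s + us_antipeak,
    rebound_auc = us_offset_s + rebound_auc,
    baseline = baseline
  )
}

#' Extract per-trial features from a peri-event matrix
#'
#' For each trial: the CS peak (maximum z in the CS window), US peak
#' (maximum in the US-onset window), US anti-peak (signed minimum in the
#' anti-peak window), integrated post-US rebound (trapezoidal area under z
#' over the rebound window, in z-seconds), and the baseline-window mean.
#' Windows are anchored in time relative to the event, so a one-sample shift
#' of the event within the session leaves features unchanged.
#'
#' @param mat a `perievent_matrix` from [extract_perievent()].
#' @param windows a window list from [feature_windows()]; every window must
#'   lie inside the matrix window and contain at least one sample.
#' @return tibble with one row per trial: `trial`, `cs_peak_z`, `us_peak_z`,
#'   `us_antipeak_z`, `rebound_auc_zs`, `baseline_mean_z`.
#' @export
extract_trial_features <- function(mat, windows = feature_windows()) {
  check_columns(mat, c("trial", "time_rel_s", "z"), "`mat`")
  win <- attr(mat, "window")
  rel <- mat$time_rel_s[mat$trial == mat$trial[1]]
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2 || w[2] < w[1]) {
      abort(sprintf("Window `%s` must be (lo, hi) with hi >= lo.", nm))
    }
    if (!is.null(win) && (w[1] < -win[["pre_s"]] - 1e-9 || w[2] > win[["post_s"]] + 1e-9)) {
      abort(sprintf(
        "Window `%s` [%g, %g] s lies outside the matrix window [%g, %g] s.",
        nm, w[1], w[2], -win[["pre_s"]], win[["post_s"]]
      ))
    }
    if (!any(rel >= w[1] & rel <= w[2])) {
      abort(sprintf("Window `%s` [%g, %g] s contains no samples.", nm, w[1], w[2]))
    }
  }
  in_win <- function(t, w) t >= w[1] - 1e-12 & t <= w[2] + 1e-12
  mat |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      cs_peak_z = max(.data$z[in_win(.data$time_rel_s, windows$cs_peak)]),
      us_peak_z = max(.data$z[in_win(.data$time_rel_s, windows$us_peak)]),
      us_antipeak_z = min(.data$z[in_win(.data$time_rel_s, windows$us_antipeak)]),
      rebound_auc_zs = {
        sel <- in_win(.data$time_rel_s, windows$rebound_auc)
        pracma::trapz(.data$time_rel_s[sel], .data$z[sel])
      },
      baseline_mean_z = mean(.data$z[in_win(.data$time_rel_s, windows$baseline)]),
      .groups = "drop"
    )
}

#' Paired contrast of US responses on rewarded versus omission trials
#'
#' Joins per-subject mean US peak responses from rewarded and omission
#' trials and tests the paired difference (rewarded − omission) with a
#' paired t test. Subjects present in only one condition are excluded and
#' reported in attribute `"excluded"`.
#'
#' @param rewarded,omission tibbles with columns `subject`, `us_peak_z`
#'   (one row per subject; per-subject trial means).
#' @return one-row tibble: `n_pairs`, `mean_rewarded`, `mean_omission`,
#'   `mean_diff`, `statistic`, `df`, `p.value`, `method`.
#' @export
omission_contrast <- function(rewarded, omission) {
  check_columns(rewarded, c("subject", "us_peak_z"), "`rewarded`")
  check_columns(omission, c("subject", "us_peak_z"), "`omission`")
  paired <- dplyr::inner_join(
    rewarded, omission,
    by = "subject", suffix = c("_rewarded", "_omission")
  )
  excluded <- setdiff(
    union(rewarded$subject, omission$subject), paired$subject
  )
  if (nrow(paired) < 2) {
    abort("Need at least 2 paired subjects for the omission contrast.")
  }
  d <- paired$us_peak_z_rewarded - paired$us_peak_z_omission
  if (sd(d) == 0) {
    res <- tibble(statistic = NA_real_, df = length(d) - 1, p.value = NA_real_)
  } else {
    ht <- stats::t.test(paired$us_peak_z_rewarded, paired$us_peak_z_omission,
                        paired = TRUE)
    res <- tibble(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p.value = ht$p.value
    )
  }
  out <- dplyr::bind_cols(
    tibble(
      n_pairs = nrow(paired),
      mean_rewarded = mean(paired$us_peak_z_rewarded),
      mean_omission = mean(paired$us_peak_z_omission),
      mean_diff = mean(d)
    ),
    res,
    tibble(method = "paired t-test")
  )
  attr(out, "excluded") <- excluded
  if (length(excluded) > 0) {
    warn(sprintf(
      "%d unpaired subject%s excluded: %s.",
      length(excluded), if (length(excluded) > 1) "s" else "",
      paste(excluded, collapse = ", ")
    ))
  }
  out
}

#' Linear trend of a feature across trials or sessions
#'
#' Ordinary least-squares line of a per-trial (or per-session) feature
#' against its ordinal index. The slope is the "rate of change" statistic
#' used to relate signal dynamics to behavioral learning rates. For a
#' zero-variance (constant) series the fit is exact and `r2` is reported as
#' 0 by convention.
#'
#' @param df data frame holding the series.
#' @param value name of the value column (default `"value"`).
#' @param index name of the index column; `NULL` (default) uses the 1-based
#'   row order.
#' @return one-row tibble: `slope`, `intercept`, `r2`, `n`, with the
#'   underlying `lm` fit in attribute `"model"`.
#' @examples
#' feature_trend(tibble::tibble(value = c(1, 3, 5, 7)))
#' @export
feature_trend <- function(df, value = "value", index = NULL) {
  check_columns(df, value, "`df`")
  y <- df[[value]]
  x <- if (is.null(index)) seq_along(y) else df[[index]]
  if (length(y) < 3) abort("`feature_trend()` needs at least 3 points.")
  fit <- lm(y ~ x)
  if (var(y) == 0) {
    # a constant series is an exact zero-slope fit; r2 is 0 by convention
    out <- tibble(slope = 0, intercept = y[1], r2 = 0, n = length(y))
    attr(out, "model") <- fit
    return(out)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  out <- tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = r2,
    n = length(y)
  )
  attr(out, "model") <- fit
  out
}
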