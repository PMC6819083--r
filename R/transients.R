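# --- peak machinery -------------------------------------------------------
# Strict local maxima; for plateaus the first (earliest) sample is the peak.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  sv <- s[nz]
  k <- which(sv[-length(sv)] == 1 & sv[-1] == -1)
  nz[k] + 1L
}

# Topographic prominence of each peak: height minus the higher of the two
# base levels, where each base is the minimum of the trace between the peak
# and the nearest strictly higher sample on that side (or the trace end).
# Computed exactly on the compressed alternating extrema sequence, with the
# trace endpoints acting as boundary candidates.
peak_prominences <- function(x, peaks) {
  m <- length(peaks)
  if (m == 0) return(numeric(0))
  n <- length(x)
  hv <- x[peaks]
  # valleys between consecutive peaks, plus the two boundary segments
  seg_min <- function(a, b) min(x[a:b])
  val_left0 <- seg_min(1L, peaks[1])                    # start .. first peak
  val_right0 <- seg_min(peaks[m], n)                    # last peak .. end
  vals <- if (m > 1) {
    vapply(seq_len(m - 1), function(j) seg_min(peaks[j], peaks[j + 1]), numeric(1))
  } else {
    numeric(0)
  }
  b0 <- x[1]
  b1 <- x[n]
  prom <- numeric(m)
  for (k in seq_len(m)) {
    h <- hv[k]
    # left scan over compressed peaks; boundary value x[1] terminates
    cur <- if (k == 1) val_left0 else vals[k - 1]
    j <- k - 1L
    while (j >= 1L && hv[j] <= h) {
      cur <- min(cur, if (j == 1L) val_left0 else vals[j - 1L])
      j <- j - 1L
    }
    lb <- if (j >= 1L || b0 > h) cur else min(cur, b0)
    # right scan
    cur <- if (k == m) val_right0 else vals[k]
    j <- k + 1L
    while (j <= m && hv[j] <= h) {
      cur <- min(cur, if (j == m) val_right0 else vals[j])
      j <- j + 1L
    }
    rb <- if (j <= m || b1 > h) cur else min(cur, b1)
    prom[k] <- h - max(lb, rb)
  }
  prom
}

# full width at the reference level, by linear interpolation of the flank
# crossings around peak index i; NA when a flank never crosses the level.
peak_width_at <- function(x, time_s, i, level) {
  h <- x[i]
  if (level >= h) return(NA_real_)
  left <- NA_real_
  if (i > 1) {
    below <- which(x[seq_len(i - 1)] < level)
    if (length(below) > 0) {
      j <- max(below)
      left <- time_s[j] +
        (level - x[j]) / (x[j + 1] - x[j]) * (time_s[j + 1] - time_s[j])
    }
  }
  right <- NA_real_
  if (i < length(x)) {
    below <- which(x[seq.int(i + 1, length(x))] < level)
    if (length(below) > 0) {
      j <- i + min(below)
      right <- time_s[j - 1] +
        (x[j - 1] - level) / (x[j - 1] - x[j]) * (time_s[j] - time_s[j - 1])
    }
  }
  right - left
}

# --- user-facing detection ------------------------------------------------

#' Detect transients on a normalized trace
#'
#' Peaks are strict local maxima of the trace whose topographic prominence
#' reaches `threshold_z` (the conventional two-z-score threshold suppresses
#' fluorescence noise). Plateau ties resolve to the earliest sample. Peaks
#' closer together than `min_separation_s` are reduced to the larger (then
#' earlier) one. The full width at half maximum is measured at half the
#' peak's prominence (or half its absolute height, see `fwhm_at`) by linear
#' interpolation of the flank crossings.
#'
#' The session transient rate is `count / analyzed duration`, where the
#' analyzed duration excludes edge-flagged samples (column `edge`, added by
#' [demodulate_session()] and propagated by [process_session()]); peaks in
#' the excluded region are dropped.
#'
#' @param x tibble with columns `time_s` and the normalized trace (default
#'   column `"z"`, e.g. from [process_session()]); a `dff` column, when
#'   present, feeds the median-fluorescence summary.
#' @param threshold_z detection threshold in z units (default 2, > 0).
#' @param min_separation_s minimal separation between reported peaks in
#'   seconds (default 0.2).
#' @param fwhm_at `"half_prominence"` (default) or `"half_height"`.
#' @param col name of the trace column (default `"z"`).
#' @return a `transient_table`: tibble with columns `peak_time_s`,
#'   `height_z`, `prominence_z`, `fwhm_s`, sorted by time, with the session
#'   summary (rate, mean height, mean FWHM, median dF/F, analyzed duration)
#'   in attribute `"summary"` and available via [glance()]. An empty table
#'   is a valid result.
#' @examples
#' tr <- seq(0, 60, by = 1 / 50)
#' z <- 4 * exp(-((tr - 30) / 0.2)^2 / 2)
#' detect_transients(tibble::tibble(time_s = tr, z = z))
#' @export
detect_transients <- function(x,
                              threshold_z = 2,
                              min_separation_s = 0.2,
                              fwhm_at = c("half_prominence", "half_height"),
                              col = "z") {
  fwhm_at <- match.arg(fwhm_at)
  check_columns(x, c("time_s", col), "`x`")
  if (!is.numeric(threshold_z) || threshold_z <= 0) {
    abort("`threshold_z` must be > 0.")
  }
  z <- x[[col]]
  time_s <- x$time_s
  fs <- check_uniform_time(time_s)
  edge <- if ("edge" %in% names(x)) x$edge else rep(FALSE, length(z))
  analyzed_s <- sum(!edge) / fs

  peaks <- find_local_maxima(z)
  prom <- peak_prominences(z, peaks)
  keep <- prom >= threshold_z & !edge[peaks]
  peaks <- peaks[keep]
  prom <- prom[keep]

  if (length(peaks) > 1 && min_separation_s > 0) {
    ord <- order(-z[peaks], time_s[peaks])
    accepted <- logical(length(peaks))
    acc_t <- numeric(0)
    for (i in ord) {
      ti <- time_s[peaks[i]]
      if (length(acc_t) == 0 || all(abs(ti - acc_t) >= min_separation_s)) {
        accepted[i] <- TRUE
        acc_t <- c(acc_t, ti)
      }
    }
    peaks <- peaks[accepted]
    prom <- prom[accepted]
  }

  ord <- order(peaks)
  peaks <- peaks[ord]
  prom <- prom[ord]

  fwhm <- vapply(seq_along(peaks), function(k) {
    level <- if (fwhm_at == "half_prominence") {
      z[peaks[k]] - prom[k] / 2
    } else {
      z[peaks[k]] / 2
    }
    peak_width_at(z, time_s, peaks[k], level)
  }, numeric(1))

  out <- tibble(
    peak_time_s = time_s[peaks],
    height_z = z[peaks],
    prominence_z = prom,
    fwhm_s = fwhm
  )
  summary <- tibble(
    n = nrow(out),
    rate_hz = if (analyzed_s > 0) nrow(out) / analyzed_s else NA_real_,
    mean_height_z = if (nrow(out)) mean(out$height_z) else NA_real_,
    mean_fwhm_s = if (nrow(out)) mean(out$fwhm_s, na.rm = TRUE) else NA_real_,
    median_dff = if ("dff" %in% names(x)) median(x$dff[!edge]) else NA_real_,
    analyzed_s = analyzed_s
  )
  attr(out, "summary") <- summary
  attr(out, "threshold_z") <- threshold_z
  class(out) <- c("transient_table", class(out))
  out
}

#' @method glance transient_table
#' @export
glance.transient_table <- function(x, ...) {
  attr(x, "summary")
}

#' Per-epoch baseline summaries and their subject mean
#'
#' Splits a processed trace and its detected transients into recording
#' epochs (e.g. repeated 5-min spontaneous recordings) and reports, per
#' epoch, the transient rate, mean peak height, mean FWHM and median dF/F.
#' Subject-level values are the unweighted means across epochs, following
#' the convention of averaging outputs within each subject across repeated
#' recordings.
#'
#' @param x processed trace tibble with columns `time_s`, `dff` (and
#'   optionally `z`, `edge`).
#' @param transients a `transient_table` from [detect_transients()].
#' @param epochs tibble/data frame with columns `start_s`, `end_s`; every
#'   epoch must lie inside the trace.
#' @return tibble with one row per epoch (`epoch`, `start_s`, `end_s`,
#'   `rate_hz`, `mean_height_z`, `mean_fwhm_s`, `median_dff`) and the
#'   across-epoch subject mean in attribute `"subject_mean"`.
#' @export
summarize_baseline <- function(x, transients, epochs) {
  check_columns(x, c("time_s", "dff"), "`x`")
  check_columns(epochs, c("start_s", "end_s"), "`epochs`")
  check_columns(transients, c("peak_time_s", "height_z", "fwhm_s"), "`transients`")
  t0 <- min(x$time_s)
  t1 <- max(x$time_s)
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(epochs)), epochs$start_s, epochs$end_s),
    function(i, a, b) {
      if (a < t0 - 1e-9 || b > t1 + 1e-9 || b <= a) {
        abort(sprintf(
          "Epoch %d [%g, %g] s lies outside the trace [%g, %g] s.", i, a, b, t0, t1
        ))
      }
      hit <- transients$peak_time_s >= a & transients$peak_time_s < b
      in_ep <- x$time_s >= a & x$time_s < b
      tibble(
        epoch = i, start_s = a, end_s = b,
        rate_hz = sum(hit) / (b - a),
        mean_height_z = if (any(hit)) mean(transients$height_z[hit]) else NA_real_,
        mean_fwhm_s = if (any(hit)) mean(transients$fwhm_s[hit], na.rm = TRUE) else NA_real_,
        median_dff = median(x$dff[in_ep])
      )
    }
  )
  attr(out, "subject_mean") <- dplyr::summarise(
    out,
    dplyr::across(c("rate_hz", "mean_height_z", "mean_fwhm_s", "median_dff"),
                  ~ mean(.x, na.rm = TRUE))
  )
  out
}

#' Score detected transients against known event times
#'
#' Tolerance-window matching: a detection is a true positive if a reference
#' time lies within `tolerance_s` of it, and a reference event is recalled
#' if a detection lies within `tolerance_s` of it. Events closer together
#' than the kernel's resolvable separation can share one detection, so the
#' two rates are computed per side rather than as a forced one-to-one
#' pairing.
#'
#' @param detected numeric vector of detected peak times (s), or a
#'   `transient_table`.
#' @param reference numeric vector of ground-truth event times (s).
#' @param tolerance_s matching tolerance in seconds (default 0.25).
#' @param reference_lag_s expected lag of the measured peak after the event
#'   time (e.g. the transient kernel's rise-to-peak time); added to
#'   `reference` before matching (default 0).
#' @return one-row tibble: `n_detected`, `n_reference`, `precision`,
#'   `recall`.
#' @export
match_transients <- function(detected, reference, tolerance_s = 0.25,
                             reference_lag_s = 0) {
  if (is.data.frame(detected)) detected <- detected$peak_time_s
  ref <- sort(reference) + reference_lag_s
  det <- sort(detected)
  near <- function(a, b) {
    # for each element of a, is some element of sorted b within tolerance?
    if (length(b) == 0) return(rep(FALSE, length(a)))
    idx <- findInterval(a, b)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(b))
    abs(a - b[lo]) <= tolerance_s | abs(a - b[hi]) <= tolerance_s
  }
  tibble(
    n_detected = length(det),
    n_reference = length(ref),
    precision = if (length(det)) mean(near(det, ref)) else NA_real_,
    recall = if (length(ref)) mean(near(ref, det)) else NA_real_
  )
}
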