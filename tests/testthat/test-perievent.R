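# a session trace with a known waveform placed at each event:
# z = 3 spike at +0.5 s, -2 spike at +1.5 s, unit rectangle over [+2, +4] s
constructed_session <- function(event_times, fs = 100, duration_s = 120,
                                jitter_samples = 0) {
  n <- duration_s * fs + 1
  z <- rep(0, n)
  t <- (0:(n - 1)) / fs
  for (te in event_times) {
    i0 <- round(te * fs) + 1 + jitter_samples
    z[i0 + 0.5 * fs] <- 3
    z[i0 + 1.5 * fs] <- -2
    rect <- (i0 + 2 * fs):(i0 + 4 * fs)
    z[rect] <- 1
  }
  tibble::tibble(time_s = t, z = z)
}

test_that("trials are exact slices in event order", {
  df <- constructed_session(c(20, 50, 80))
  ev <- tibble::tibble(time_s = c(20, 50, 80), label = "US_ON")
  mat <- extract_perievent(df, ev, "US_ON", pre_s = 2, post_s = 8)
  expect_identical(dplyr::n_distinct(mat$trial), 3L)
  n_row <- sum(mat$trial == 1)
  expect_identical(n_row, as.integer(10 * 100 + 1))
  # row 1 equals the raw slice around the first event
  i0 <- round(20 * 100) + 1
  expect_identical(mat$z[mat$trial == 1], df$z[(i0 - 200):(i0 + 800)])
})

test_that("many events give one row each, in order", {
  sched <- simulate_trial_schedule("pavlovian", n_trials = 20, seed = 3,
                                   start_offset_s = 20)
  df <- tibble::tibble(
    time_s = seq(0, max(sched$onset_s) + 30, by = 1 / 50),
    z = 0
  )
  ev <- schedule_events(sched)
  mat <- extract_perievent(df, ev, "CS_ON", pre_s = 5, post_s = 10)
  expect_identical(dplyr::n_distinct(mat$trial), 20L)
  first_of_trial <- mat |>
    dplyr::distinct(.data$trial, .data$event_time_s)
  expect_identical(first_of_trial$event_time_s, sched$onset_s)
})

test_that("truncated windows drop the trial and report it", {
  df <- constructed_session(c(1, 50))
  ev <- tibble::tibble(time_s = c(1, 50), label = "US_ON")
  expect_warning(
    mat <- extract_perievent(df, ev, "US_ON", pre_s = 5, post_s = 8),
    "dropped"
  )
  expect_identical(dplyr::n_distinct(mat$trial), 1L)
  expect_identical(nrow(attr(mat, "dropped")), 1L)
  expect_equal(attr(mat, "dropped")$event_time_s, 1)
})

test_that("constructed waveform features match their analytic values", {
  df <- constructed_session(c(20, 50))
  ev <- tibble::tibble(time_s = c(20, 50), label = "US_ON")
  mat <- extract_perievent(df, ev, "US_ON", pre_s = 2, post_s = 8)
  feats <- extract_trial_features(mat)
  expect_identical(nrow(feats), 2L)
  expect_equal(feats$cs_peak_z, c(3, 3))
  expect_equal(feats$us_peak_z, c(3, 3))
  expect_equal(feats$us_antipeak_z, c(-2, -2))
  expect_equal(feats$rebound_auc_zs, c(2, 2), tolerance = 0.02)
  expect_equal(feats$baseline_mean_z, c(0, 0))
})

test_that("a one-sample shift of the waveform leaves features unchanged", {
  ev <- tibble::tibble(time_s = 60, label = "US_ON")
  base <- extract_trial_features(
    extract_perievent(constructed_session(60), ev, "US_ON", 2, 8)
  )
  shifted_df <- constructed_session(60, jitter_samples = 1)
  shifted_ev <- tibble::tibble(time_s = 60 + 1 / 100, label = "US_ON")
  shifted <- extract_trial_features(
    extract_perievent(shifted_df, shifted_ev, "US_ON", 2, 8)
  )
  expect_equal(shifted[, -1], base[, -1])
})

test_that("features commute with trial order and AUC is linear", {
  df <- constructed_session(c(20, 50, 80))
  ev <- tibble::tibble(time_s = c(20, 50, 80), label = "US_ON")
  mat <- extract_perievent(df, ev, "US_ON", 2, 8)
  feats <- extract_trial_features(mat)
  reordered <- mat[order(-mat$trial, mat$time_rel_s), ]
  feats2 <- extract_trial_features(reordered)
  expect_equal(dplyr::arrange(feats2, trial), feats)

  neg <- mat
  neg$z <- -neg$z
  expect_equal(
    extract_trial_features(neg)$rebound_auc_zs,
    -feats$rebound_auc_zs
  )
})

test_that("windows outside the matrix are rejected", {
  df <- constructed_session(30)
  ev <- tibble::tibble(time_s = 30, label = "US_ON")
  mat <- extract_perievent(df, ev, "US_ON", 2, 8)
  expect_error(
    extract_trial_features(mat, feature_windows(rebound_auc = c(2, 12))),
    "rebound_auc"
  )
})

test_that("omission contrast handles identity, shifts, and hand-computed t", {
  rewarded <- tibble::tibble(subject = 1:3, us_peak_z = c(1, 2, 4))
  expect_equal(omission_contrast(rewarded, rewarded)$mean_diff, 0)

  omission <- tibble::tibble(subject = 1:3, us_peak_z = c(1, 2, 4) - 1)
  shifted <- omission_contrast(rewarded, omission)
  expect_equal(shifted$mean_diff, 1)

  om2 <- tibble::tibble(subject = 1:3, us_peak_z = c(0, 1, 1))
  res <- omission_contrast(rewarded, om2)
  # d = (1, 1, 3): mean 5/3, sd 2/sqrt(3), t = (5/3) / (2/3) = 2.5, df = 2
  expect_equal(res$statistic, 2.5, tolerance = 1e-9)
  expect_equal(res$df, 2)

  extra <- dplyr::bind_rows(
    rewarded, tibble::tibble(subject = 4, us_peak_z = 9)
  )
  expect_warning(out <- omission_contrast(extra, om2), "unpaired")
  expect_identical(out$n_pairs, 3L)
})

test_that("feature trends recover slopes and degenerate cases", {
  expect_equal(feature_trend(tibble::tibble(value = rep(2, 5)))$slope, 0)
  expect_equal(feature_trend(tibble::tibble(value = rep(2, 5)))$r2, 0)
  lineal <- feature_trend(tibble::tibble(value = 2 * (1:10)))
  expect_equal(lineal$slope, 2, tolerance = 1e-12)
  expect_equal(lineal$r2, 1)
  expect_error(feature_trend(tibble::tibble(value = c(1, 2))), "3 points")

  set.seed(16)
  hits <- vapply(1:200, function(i) {
    y <- 0.5 * (1:10) + rnorm(10, 0, 1)
    sign(feature_trend(tibble::tibble(value = y))$slope) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
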