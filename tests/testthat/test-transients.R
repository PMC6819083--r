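test_that("a flat trace yields an empty table with zero rate", {
  out <- detect_transients(make_trace(rep(0, 1000)))
  expect_identical(nrow(out), 0L)
  expect_equal(glance(out)$rate_hz, 0)
})

test_that("noise-free Gaussian bumps have the analytic FWHM", {
  sigma <- 0.2
  fs <- 382
  bumps <- gaussian_bumps(
    centers_s = c(10, 25, 40, 55, 70), height = 4, sigma_s = sigma,
    duration_s = 80, fs = fs
  )
  out <- detect_transients(bumps)
  expect_identical(nrow(out), 5L)
  expect_equal(out$height_z, rep(4, 5), tolerance = 1e-3)
  analytic <- 2 * sqrt(2 * log(2)) * sigma
  expect_true(all(abs(out$fwhm_s - analytic) <= 1 / fs))
})

test_that("sub-threshold bumps are not detected", {
  bump <- gaussian_bumps(30, height = 1.9, sigma_s = 0.3, duration_s = 60)
  expect_identical(nrow(detect_transients(bump, threshold_z = 2)), 0L)
})

test_that("raising the threshold never increases the detection count", {
  set.seed(13)
  z <- as.numeric(robust_z(cumsum(rnorm(3000)) / 10 + rnorm(3000)))
  df <- make_trace(z)
  counts <- vapply(
    seq(0.5, 6, by = 0.25),
    function(th) nrow(detect_transients(df, threshold_z = th)),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("detection equals the brute-force prominence oracle", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(200:2000, 1)
    z <- rnorm(n)
    # include plateau-heavy quantized traces on some repetitions
    if (rep %% 2 == 0) z <- round(z, 1)
    df <- make_trace(z)
    th <- runif(1, 0.5, 3)
    got <- detect_transients(df, threshold_z = th, min_separation_s = 0)
    want_idx <- oracle_detect_peaks(z, th)
    expect_equal(got$peak_time_s, df$time_s[want_idx])
  }
})

test_that("close peaks are reduced to the larger, then earlier one", {
  fs <- 100
  z <- rep(0, 500)
  z[101] <- 5
  z[106] <- 4 # 0.05 s later, smaller: dropped at 0.2 s separation
  z[300] <- 3
  z[305] <- 3 # equal height plateau-free tie: earlier wins
  df <- make_trace(z, fs = fs)
  out <- detect_transients(df, threshold_z = 2, min_separation_s = 0.2)
  expect_equal(out$peak_time_s, c(1.00, 2.99))
  expect_equal(out$height_z, c(5, 3))
})

test_that("plateau peaks report their earliest sample", {
  z <- c(rep(0, 10), 1, 3, 3, 3, 1, rep(0, 10))
  out <- detect_transients(make_trace(z, fs = 10), threshold_z = 2)
  expect_identical(nrow(out), 1L)
  expect_equal(out$peak_time_s, 1.1) # index 12, the first plateau sample
})

test_that("detection ignores constant offsets of the raw dF/F trace", {
  set.seed(15)
  dff <- rep(0, 2000)
  for (ctr in c(400, 900, 1500)) {
    dff[ctr:(ctr + 80)] <- dff[ctr:(ctr + 80)] + 0.05 * exp(-(0:80) / 30)
  }
  dff <- dff + rnorm(2000, 0, 0.002)
  t1 <- detect_transients(robust_z(make_trace(dff, col = "dff")))
  t2 <- detect_transients(robust_z(make_trace(dff + 0.37, col = "dff")))
  expect_equal(t1$peak_time_s, t2$peak_time_s)
  expect_equal(t1$height_z, t2$height_z, tolerance = 1e-9)
})

test_that("edge-flagged samples are excluded from peaks and duration", {
  fs <- 100
  z <- rep(0, 1000)
  z[50] <- 5 # inside the leading edge-flagged second
  z[500] <- 5
  df <- make_trace(z, fs = fs)
  df$edge <- df$time_s < 1 | df$time_s > max(df$time_s) - 1
  out <- detect_transients(df)
  expect_identical(nrow(out), 1L)
  expect_equal(glance(out)$analyzed_s, sum(!df$edge) / fs)
})

test_that("baseline epoch summaries average as hand-computed", {
  fs <- 50
  z <- rep(0, 300 * fs + 1)
  peak_times <- c(seq(5, 95, by = 10), seq(105, 155, by = 10), seq(205, 295, by = 10))
  z[round(peak_times * fs) + 1] <- 5
  df <- make_trace(z, fs = fs)
  df$dff <- z * 0.01 + 0.002
  tr <- detect_transients(df)
  one <- summarize_baseline(df, tr, tibble::tibble(start_s = 0, end_s = 300))
  expect_equal(one$rate_hz, length(peak_times) / 300)

  epochs <- tibble::tibble(start_s = c(0, 100, 200), end_s = c(100, 200, 300))
  per <- summarize_baseline(df, tr, epochs)
  expect_equal(per$rate_hz, c(10, 6, 10) / 100)
  sm <- attr(per, "subject_mean")
  expect_equal(sm$rate_hz, mean(c(0.10, 0.06, 0.10)))

  same <- summarize_baseline(
    df, tr, tibble::tibble(start_s = rep(0, 3), end_s = rep(300, 3))
  )
  expect_equal(attr(same, "subject_mean")$rate_hz, same$rate_hz[1])

  expect_error(
    summarize_baseline(df, tr, tibble::tibble(start_s = -5, end_s = 50)),
    "Epoch 1"
  )
})

test_that("transient scoring matches hand counts on a constructed case", {
  det <- c(1.0, 5.0, 9.0)
  truth <- c(1.1, 5.05, 20)
  m <- match_transients(det, truth, tolerance_s = 0.25)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
})
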