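# cheap noise-free configuration used where only event timing matters
quiet_cfg <- function(duration_s, seed, ...) {
  sim_config(
    duration_s = duration_s, fs_raw = 1528, fs_out = 382,
    motion_amp = 0, noise_sd = 0, bleach_tau_s = Inf, seed = seed, ...
  )
}

test_that("identical config and seed give bit-identical sessions", {
  a <- simulate_session(sim_config(duration_s = 5, seed = 11))
  b <- simulate_session(sim_config(duration_s = 5, seed = 11))
  expect_identical(a$raw, b$raw)
  expect_identical(a$truth, b$truth)
  c <- simulate_session(sim_config(duration_s = 5, seed = 12))
  expect_false(identical(a$raw$detector_v, c$raw$detector_v))
})

test_that("zero transient rate gives empty ground truth and zero dff", {
  sim <- simulate_session(quiet_cfg(5, seed = 2, transient_rate_hz = 0))
  expect_length(sim$truth$transient_times, 0)
  expect_true(all(sim$truth$traces$dff == 0))
})

test_that("with all noise sources off the raw trace is two pure sinusoids", {
  cfg <- sim_config(
    duration_s = 2, motion_amp = 0, noise_sd = 0, bleach_tau_s = Inf,
    transient_rate_hz = 0, seed = 3
  )
  sim <- simulate_session(cfg)
  t <- sim$raw$time_s
  expected <- cfg$amp_490 * sin(2 * pi * 211 * t) + cfg$amp_405 * sin(2 * pi * 531 * t)
  expect_equal(sim$raw$detector_v, expected, tolerance = 1e-12)
})

test_that("carriers at or above the raw Nyquist are rejected by name", {
  expect_error(
    sim_config(fs_raw = 764, fs_out = 382, carrier_405_hz = 531),
    "carrier_405_hz"
  )
  expect_error(sim_config(fs_raw = 6112, fs_out = 381), "integer multiple")
})

test_that("transient count for the reference condition is reproducible", {
  # 600 s at 0.5 events/s; count pinned from a frozen run of this generator
  sim <- simulate_session(quiet_cfg(600, seed = 1))
  expect_identical(length(sim$truth$transient_times), 311L)
  expect_true(all(diff(sim$truth$transient_times) > 0))
  expect_true(all(sim$truth$transient_times >= 0 & sim$truth$transient_times <= 600))
  expect_identical(nrow(sim$truth$traces), 600L * 382L)
})

test_that("mean transient count converges to the configured rate", {
  counts <- vapply(1:30, function(s) {
    length(simulate_session(quiet_cfg(100, seed = 100 + s))$truth$transient_times)
  }, numeric(1))
  total_s <- 30 * 100
  rate_hat <- sum(counts) / total_s
  se <- sqrt(0.5 / total_s)
  expect_lt(abs(rate_hat - 0.5), 3 * se)
})

test_that("the two largest off-DC spectral peaks sit at the carriers", {
  sim <- simulate_session(sim_config(
    duration_s = 10, motion_amp = 0, noise_sd = 0, bleach_tau_s = Inf, seed = 4
  ))
  v <- sim$raw$detector_v
  n <- length(v)
  spec <- Mod(stats::fft(v))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * 6112 / n
  spec[freq < 5] <- 0 # drop DC/very-low-frequency bins
  top2 <- freq[order(spec, decreasing = TRUE)[1:2]]
  expect_equal(sort(top2), c(211, 531), tolerance = 0.2)
})

test_that("pavlovian schedules space trials by CS + uniform ITI", {
  sched <- simulate_trial_schedule("pavlovian", n_trials = 20, seed = 5)
  expect_identical(nrow(sched), 20L)
  gaps <- diff(sched$onset_s)
  expect_true(all(gaps >= 85 & gaps <= 115))
  expect_true(all(sched$us_offset_s == 7))
  expect_true(all(sched$cs_duration_s == 10))
  # determinism and the single-trial session start
  sched2 <- simulate_trial_schedule("pavlovian", n_trials = 20, seed = 5)
  expect_identical(sched$onset_s, sched2$onset_s)
  one <- simulate_trial_schedule("fear", n_trials = 1, seed = 6, start_offset_s = 45)
  expect_identical(one$onset_s, 45)
  expect_error(simulate_trial_schedule("operant", n_trials = 5), "pavlovian")
})

test_that("schedule events carry the US markers of their paradigm", {
  pav <- simulate_trial_schedule("pavlovian", n_trials = 3, seed = 7)
  ev <- schedule_events(pav)
  expect_identical(sum(ev$label == "CS_ON"), 3L)
  expect_identical(sum(ev$label == "PUMP"), 3L)
  expect_equal(
    ev$time_s[ev$label == "PUMP"], pav$onset_s + 7
  )
  fear <- simulate_trial_schedule("fear", n_trials = 4, seed = 8)
  fev <- schedule_events(fear)
  expect_identical(sum(fev$label == "SHOCK_ON"), 4L)
  expect_equal(fev$time_s[fev$label == "SHOCK_ON"], fear$onset_s + 10)
  stim <- simulate_trial_schedule("stimulus", n_trials = 10, seed = 9)
  expect_true(all(stim$label %in% c("LIGHT_ON", "TONE_ON")))
})

test_that("lick trains stay inside their bouts at about the stated rate", {
  one <- simulate_lick_train(
    tibble::tibble(onset_s = 5, rate_hz = 10, duration_s = 1), seed = 10
  )
  expect_true(all(one >= 5 & one < 6))
  expect_true(abs(length(one) - 10) <= 1)
  expect_length(
    simulate_lick_train(tibble::tibble(
      onset_s = numeric(), rate_hz = numeric(), duration_s = numeric()
    ), seed = 1),
    0
  )
  two <- simulate_lick_train(
    tibble::tibble(onset_s = c(0, 6), rate_hz = 10, duration_s = 1), seed = 11
  )
  gap <- min(two[two >= 6]) - max(two[two < 1])
  expect_gte(gap, 5)
  expect_error(
    simulate_lick_train(
      tibble::tibble(onset_s = c(0, 0.5), rate_hz = 10, duration_s = 1), seed = 1
    ),
    "overlap"
  )
})

test_that("toy morphologies have exactly the advertised geometry", {
  rad <- simulate_morphology("radial", length_um = 23)
  expect_identical(sum(rad$parent == -1), 1L)
  expect_equal(max(rad$x), 23)
  expect_true(all(rad$y == 0 & rad$z == 0))

  soma <- simulate_morphology("soma_only")
  expect_identical(nrow(soma), 1L)

  yb <- simulate_morphology("y_branch", length_um = 30, branch_at_um = 12)
  leaves <- yb[!(yb$id %in% yb$parent), ]
  expect_identical(nrow(leaves), 2L)
  tip_d <- sqrt(leaves$x^2 + leaves$y^2 + leaves$z^2)
  expect_equal(tip_d, c(30, 30), tolerance = 1e-9)
  expect_error(simulate_morphology("radial", length_um = -3), "non-negative")
})
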