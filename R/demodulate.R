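#' Quadrature lock-in demodulation of one carrier
#'
#' Recovers the slowly varying amplitude of one amplitude-modulated carrier
#' from the raw photodetector trace by sine-reference quadrature lock-in:
#' \deqn{a(t) = 2\sqrt{LP[x \sin(2\pi f_c t)]^2 + LP[x \cos(2\pi f_c t)]^2}}
#' where `LP` is the zero-phase Butterworth low-pass of
#' [lowpass_zero_phase()]. The factor 2 makes the output equal the carrier
#' amplitude: for `x = A sin(2 pi f_c t + phi)` with `A` slowly varying the
#' output is `A`, independent of the carrier phase.
#'
#' @param raw tibble with columns `time_s`, `detector_v` at a uniform raw
#'   sampling rate (e.g. from [simulate_session()]`$raw`).
#' @param carrier_hz carrier frequency in Hz; must be below the raw Nyquist
#'   frequency.
#' @param lp_cutoff_hz lock-in low-pass cutoff in Hz (default 25, the final
#'   signal bandwidth); must be below `carrier_hz`.
#' @return tibble with columns `time_s`, `envelope` at the raw rate.
#' @export
lock_in_demodulate <- function(raw, carrier_hz, lp_cutoff_hz = 25) {
  check_columns(raw, c("time_s", "detector_v"), "`raw`")
  fs_raw <- check_uniform_time(raw$time_s)
  check_scalar_number(carrier_hz, "carrier_hz")
  if (carrier_hz >= fs_raw / 2) {
    abort(sprintf(
      "Carrier %g Hz is at or above the Nyquist frequency (%g Hz) of the raw trace.",
      carrier_hz, fs_raw / 2
    ))
  }
  if (lp_cutoff_hz >= carrier_hz) {
    abort(sprintf(
      "`lp_cutoff_hz` (%g Hz) must be below the carrier (%g Hz); the envelope is not separable.",
      lp_cutoff_hz, carrier_hz
    ))
  }
  ph <- 2 * pi * carrier_hz * raw$time_s
  i_br <- lowpass_zero_phase(raw$detector_v * sin(ph), fs_raw, lp_cutoff_hz)
  q_br <- lowpass_zero_phase(raw$detector_v * cos(ph), fs_raw, lp_cutoff_hz)
  tibble(time_s = raw$time_s, envelope = 2 * sqrt(i_br^2 + q_br^2))
}

#' Demodulate a raw recording into a two-channel photometry session
#'
#' Runs [lock_in_demodulate()] at both carriers, decimates the envelopes to
#' the output rate with [decimate_to()], and flags the first and last
#' `edge_flag_s` seconds as edge-contaminated (zero-phase filtering startup
#' transients live there; summary metrics exclude flagged samples).
#'
#' @param raw tibble with columns `time_s`, `detector_v`.
#' @param carrier_490_hz,carrier_405_hz modulation frequencies of the signal
#'   and isosbestic LEDs (defaults 211 and 531 Hz).
#' @param fs_out output sampling rate (default 382 Hz); the raw rate must be
#'   an integer multiple.
#' @param lp_cutoff_hz lock-in low-pass cutoff (default 25 Hz).
#' @param edge_flag_s duration flagged as edge-contaminated at each end
#'   (default 1 s).
#' @return session tibble with columns `time_s`, `ch490`, `ch405`, `edge`
#'   (logical) at `fs_out`, with attribute `"fs"`.
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 5, seed = 1))
#' sess <- demodulate_session(sim$raw)
#' @export
demodulate_session <- function(raw,
                               carrier_490_hz = 211,
                               carrier_405_hz = 531,
                               fs_out = 382,
                               lp_cutoff_hz = 25,
                               edge_flag_s = 1) {
  fs_raw <- check_uniform_time(raw$time_s)
  sep <- abs(carrier_490_hz - carrier_405_hz)
  if (lp_cutoff_hz >= sep / 2) {
    abort(sprintf(
      "`lp_cutoff_hz` (%g Hz) must be below half the carrier separation (%g Hz).",
      lp_cutoff_hz, sep / 2
    ))
  }
  env490 <- lock_in_demodulate(raw, carrier_490_hz, lp_cutoff_hz)$envelope
  env405 <- lock_in_demodulate(raw, carrier_405_hz, lp_cutoff_hz)$envelope
  ch490 <- decimate_to(env490, fs_raw, fs_out)
  ch405 <- decimate_to(env405, fs_raw, fs_out)
  factor <- as.integer(round(fs_raw / fs_out))
  time_s <- raw$time_s[seq.int(1L, by = factor, length.out = length(ch490))]
  n <- length(time_s)
  edge <- (time_s - time_s[1]) < edge_flag_s |
    (time_s[n] - time_s) < edge_flag_s
  out <- tibble(time_s = time_s, ch490 = ch490, ch405 = ch405, edge = edge)
  attr(out, "fs") <- fs_out
  out
}
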