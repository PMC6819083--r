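#' Zero-phase Butterworth low-pass filter
#'
#' Applies a second-order (by default) Butterworth low-pass filter forward and
#' then backward, so the net phase response is zero and the amplitude response
#' is the squared single-pass response: the DC gain is exactly 1 and the gain
#' at the cutoff frequency is 1/2 (the half-power response applied twice).
#' This is the filtering convention used by photometry acquisition pipelines
#' that low-pass demodulated fluorescence at 25 Hz.
#'
#' Edge handling uses odd (reflective) padding of three filter lengths at each
#' end before the forward-backward pass, which keeps constants exactly
#' constant and suppresses startup transients. The first and last second of a
#' filtered session should still be treated as edge-contaminated for summary
#' metrics (see [demodulate_session()]).
#'
#' @param x numeric vector, the trace to filter.
#' @param fs sampling rate of `x` in Hz.
#' @param cutoff_hz low-pass cutoff (half-power) frequency in Hz; must lie in
#'   (0, fs/2).
#' @param order filter order of the single pass (default 2).
#' @return numeric vector the same length as `x`.
#' @examples
#' fs <- 382
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 3 * t) + rnorm(length(t), sd = 0.1)
#' y <- lowpass_zero_phase(x, fs, 25)
#' @export
lowpass_zero_phase <- function(x, fs, cutoff_hz, order = 2) {
  check_scalar_number(fs, "fs")
  check_scalar_number(cutoff_hz, "cutoff_hz")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort(sprintf(
      "`cutoff_hz` (%g Hz) must lie strictly inside (0, fs/2) = (0, %g).",
      cutoff_hz, fs / 2
    ))
  }
  if (!is.numeric(x)) abort("`x` must be numeric.")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_refl(bf$b, bf$a, x)
}

# forward-backward IIR filtering with odd reflection padding and steady-state
# edge initialization: each pass starts as if the input had sat at its first
# value forever, so constants pass through exactly and startup transients are
# suppressed (same recipe as scipy's filtfilt).
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  if (n == 0) return(x)
  pad <- min(n - 1L, 3L * max(length(a), length(b)))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  one_pass <- function(v) {
    as.numeric(signal::filter(
      b, a, v,
      init.x = rep(v[1], length(b) - 1),
      init.y = rep(v[1], length(a) - 1)
    ))
  }
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Decimate a trace to a lower sampling rate
#'
#' Anti-alias low-pass filters at `0.4 * fs_out` (zero-phase Butterworth,
#' order 4) and then keeps every `fs_in/fs_out`-th sample. The rate ratio must
#' be an integer so no resampling interpolation is ever performed. With
#' `fs_in == fs_out` the input is returned untouched (the anti-alias filter is
#' bypassed).
#'
#' @param x numeric vector sampled at `fs_in`.
#' @param fs_in input sampling rate (Hz).
#' @param fs_out target sampling rate (Hz); `fs_in / fs_out` must be a whole
#'   number.
#' @return numeric vector of length `floor(length(x) / (fs_in / fs_out))`.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 1, by = 1 / 6112))
#' y <- decimate_to(x, 6112, 382)
#' @export
decimate_to <- function(x, fs_in, fs_out) {
  check_scalar_number(fs_in, "fs_in")
  check_scalar_number(fs_out, "fs_out")
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf(
      "`fs_in` (%g) must be an integer multiple of `fs_out` (%g); got ratio %g.",
      fs_in, fs_out, factor
    ))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(x)
  y <- lowpass_zero_phase(x, fs_in, 0.4 * fs_out, order = 4)
  idx <- seq.int(1L, by = factor, length.out = floor(length(x) / factor))
  y[idx]
}
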