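#' Configuration for a synthetic photometry session
#'
#' Bundles and validates every knob of the synthetic two-channel photometry
#' generator. The acquisition model follows the common lock-in photometry
#' rigs: a 490 nm signal LED modulated at 211 Hz and a 405 nm isosbestic
#' reference LED modulated at 531 Hz, summed on one photodetector, digitized
#' at a high raw rate and later demodulated and decimated to 382 Hz.
#'
#' Defaults describe a realistic spontaneous dopamine recording: Poisson
#' transients at 0.5 events/s with a 50 ms rise / 500 ms decay
#' double-exponential kernel and 5% peak dF/F, slow shared photobleaching
#' (time constant 1200 s), a shared sub-2 Hz motion artifact of 1% fractional
#' amplitude, and detector noise of 0.004 V RMS on a ~1 V carrier. The noise
#' figure follows from the femtowatt photoreceiver class these rigs use
#' (NEP ~ 7 fW/sqrt(Hz) at 1e10 V/W gain integrated over the raw Nyquist
#' band); after lock-in demodulation it leaves about 0.1% dF/F noise, so
#' 5% transients have peak SNR of a few tens early in a session, degrading
#' as photobleaching shrinks the carrier.
#'
#' @param duration_s session length in seconds (default 300, a 5-min epoch).
#' @param fs_raw raw acquisition rate in Hz; must be a positive integer
#'   multiple of `fs_out` (default `16 * 382 = 6112`).
#' @param fs_out target post-decimation rate in Hz (default 382).
#' @param carrier_490_hz,carrier_405_hz LED modulation frequencies in Hz
#'   (defaults 211 and 531); both must be below `fs_raw / 2`.
#' @param transient_rate_hz Poisson rate of dopamine transients (events/s).
#' @param transient_amp peak transient amplitude in dF/F units.
#' @param transient_tau_rise_s,transient_tau_decay_s kernel time constants (s).
#' @param bleach_tau_s photobleaching time constant in seconds (`Inf` for no
#'   bleaching). A second, faster component can be mixed in via
#'   `bleach_tau2_s` and `bleach_frac2`.
#' @param bleach_tau2_s,bleach_frac2 optional second bleaching component:
#'   time constant (s) and mixing fraction in \[0, 1\] (default 0, disabled).
#' @param motion_amp standard deviation of the shared fractional motion
#'   artifact (unitless; it multiplies both channels identically).
#' @param noise_sd white detector noise standard deviation (volts) at
#'   `fs_raw`.
#' @param amp_490,amp_405 carrier amplitudes in detector volts (arbitrary;
#'   LED power and detector gain are rig-specific).
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical sessions.
#' @return a validated list of class `"sim_config"`.
#' @seealso [simulate_session()]
#' @export
sim_config <- function(duration_s = 300,
                       fs_raw = 6112,
                       fs_out = 382,
                       carrier_490_hz = 211,
                       carrier_405_hz = 531,
                       transient_rate_hz = 0.5,
                       transient_amp = 0.05,
                       transient_tau_rise_s = 0.05,
                       transient_tau_decay_s = 0.5,
                       bleach_tau_s = 1200,
                       bleach_tau2_s = Inf,
                       bleach_frac2 = 0,
                       motion_amp = 0.01,
                       noise_sd = 0.004,
                       amp_490 = 1.0,
                       amp_405 = 0.7,
                       seed = 1L) {
  cfg <- list(
    duration_s = duration_s, fs_raw = fs_raw, fs_out = fs_out,
    carrier_490_hz = carrier_490_hz, carrier_405_hz = carrier_405_hz,
    transient_rate_hz = transient_rate_hz, transient_amp = transient_amp,
    transient_tau_rise_s = transient_tau_rise_s,
    transient_tau_decay_s = transient_tau_decay_s,
    bleach_tau_s = bleach_tau_s, bleach_tau2_s = bleach_tau2_s,
    bleach_frac2 = bleach_frac2,
    motion_amp = motion_amp, noise_sd = noise_sd,
    amp_490 = amp_490, amp_405 = amp_405, seed = as.integer(seed)
  )
  factor <- cfg$fs_raw / cfg$fs_out
  if (cfg$fs_out <= 0 || cfg$fs_raw <= 0 || abs(factor - round(factor)) > 1e-9) {
    abort("`fs_raw` must be a positive integer multiple of `fs_out`.")
  }
  for (carrier in c("carrier_490_hz", "carrier_405_hz")) {
    if (cfg[[carrier]] >= cfg$fs_raw / 2) {
      abort(sprintf(
        "`%s` (%g Hz) is at or above the raw Nyquist frequency (%g Hz).",
        carrier, cfg[[carrier]], cfg$fs_raw / 2
      ))
    }
  }
  nonneg <- c(
    "duration_s", "transient_rate_hz", "transient_amp",
    "transient_tau_rise_s", "transient_tau_decay_s", "motion_amp", "noise_sd"
  )
  for (nm in nonneg) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) ||
        cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", nm))
    }
  }
  if (cfg$bleach_frac2 < 0 || cfg$bleach_frac2 > 1) {
    abort("`bleach_frac2` must lie in [0, 1].")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %g s at %g Hz raw (-> %g Hz), carriers %g / %g Hz\n",
    x$duration_s, x$fs_raw, x$fs_out, x$carrier_490_hz, x$carrier_405_hz
  ))
  cat(sprintf(
    "  transients: %g Hz, amp %g dF/F, tau %g/%g s; bleach tau %g s; motion %g; noise %g V; seed %d\n",
    x$transient_rate_hz, x$transient_amp, x$transient_tau_rise_s,
    x$transient_tau_decay_s, x$bleach_tau_s, x$motion_amp, x$noise_sd, x$seed
  ))
  invisible(x)
}

# double-exponential transient kernel sampled at fs, normalized to unit peak
transient_kernel <- function(tau_rise_s, tau_decay_s, fs) {
  if (tau_decay_s <= 0) return(1)
  tt <- seq(0, 6 * tau_decay_s, by = 1 / fs)
  k <- if (tau_rise_s > 0) {
    exp(-tt / tau_decay_s) - exp(-tt / tau_rise_s)
  } else {
    exp(-tt / tau_decay_s)
  }
  k / max(k)
}

# run fn with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Simulate a raw two-channel photometry recording with known ground truth
#'
#' Builds the photodetector trace
#' \deqn{v(t) = \epsilon(t) + b(t)\,[A_{490}(1 + \Delta F/F(t) + m(t))
#'   \sin(2\pi f_{490} t) + A_{405}(1 + m(t)) \sin(2\pi f_{405} t)]}
#' where \eqn{\Delta F/F(t)} is a sum of double-exponential transient kernels
#' at Poisson event times, \eqn{m(t)} is a slow motion artifact shared
#' identically by both channels (the physical assumption that justifies
#' isosbestic correction), \eqn{b(t)} is a multiplicative photobleaching
#' decay shared by both channels, and \eqn{\epsilon(t)} is white detector
#' noise. All latent components are returned as ground truth at the output
#' rate, so downstream recovery can be scored exactly.
#'
#' @param config a [sim_config()].
#' @return A list of class `"photometry_sim"` with elements
#'   * `raw`: tibble with columns `time_s`, `detector_v` at `fs_raw`;
#'   * `truth`: list with `transient_times` (sorted onset times in seconds)
#'     and `traces`, a tibble (`time_s`, `dff`, `motion`, `bleach`) at
#'     `fs_out`;
#'   * `config`: the configuration used.
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 10, seed = 7))
#' head(sim$raw)
#' length(sim$truth$transient_times)
#' @export
simulate_session <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by `sim_config()`.")
  }
  cfg <- config
  n_raw <- round(cfg$duration_s * cfg$fs_raw)
  t_raw <- (seq_len(n_raw) - 1) / cfg$fs_raw

  # component sub-streams are derived deterministically from the one seed
  events <- with_seed(sub_seed(cfg$seed, 1L), function() {
    n_ev <- rpois(1, cfg$transient_rate_hz * cfg$duration_s)
    sort(runif(n_ev, 0, cfg$duration_s))
  })
  events <- events[!duplicated(events)]

  dff <- numeric(n_raw)
  if (length(events) > 0 && cfg$transient_amp > 0) {
    kern <- cfg$transient_amp *
      transient_kernel(cfg$transient_tau_rise_s, cfg$transient_tau_decay_s, cfg$fs_raw)
    lk <- length(kern)
    for (e in events) {
      i0 <- round(e * cfg$fs_raw) + 1
      if (i0 > n_raw) next
      idx <- i0:min(n_raw, i0 + lk - 1)
      dff[idx] <- dff[idx] + kern[seq_along(idx)]
    }
  }

  motion <- numeric(n_raw)
  if (cfg$motion_amp > 0) {
    motion <- with_seed(sub_seed(cfg$seed, 2L), function() {
      m <- lowpass_zero_phase(rnorm(n_raw), cfg$fs_raw, 2, order = 2)
      m <- m - mean(m)
      m * (cfg$motion_amp / sd(m))
    })
  }

  bleach <- rep(1, n_raw)
  if (is.finite(cfg$bleach_tau_s) || (cfg$bleach_frac2 > 0 && is.finite(cfg$bleach_tau2_s))) {
    b1 <- if (is.finite(cfg$bleach_tau_s)) exp(-t_raw / cfg$bleach_tau_s) else rep(1, n_raw)
    b2 <- if (is.finite(cfg$bleach_tau2_s)) exp(-t_raw / cfg$bleach_tau2_s) else rep(1, n_raw)
    bleach <- (1 - cfg$bleach_frac2) * b1 + cfg$bleach_frac2 * b2
  }

  noise <- if (cfg$noise_sd > 0) {
    with_seed(sub_seed(cfg$seed, 3L), function() rnorm(n_raw, 0, cfg$noise_sd))
  } else {
    numeric(n_raw)
  }

  detector <- noise + bleach * (
    cfg$amp_490 * (1 + dff + motion) * sin(2 * pi * cfg$carrier_490_hz * t_raw) +
    cfg$amp_405 * (1 + motion) * sin(2 * pi * cfg$carrier_405_hz * t_raw)
  )

  factor <- as.integer(round(cfg$fs_raw / cfg$fs_out))
  keep <- seq.int(1L, by = factor, length.out = floor(n_raw / factor))
  truth_traces <- tibble(
    time_s = t_raw[keep],
    dff = dff[keep],
    motion = motion[keep],
    bleach = bleach[keep]
  )

  structure(
    list(
      raw = tibble(time_s = t_raw, detector_v = detector),
      truth = list(transient_times = events, traces = truth_traces),
      config = cfg
    ),
    class = "photometry_sim"
  )
}

#' @export
print.photometry_sim <- function(x, ...) {
  cat(sprintf(
    "<photometry_sim> %g s, %d raw samples, %d ground-truth transients\n",
    x$config$duration_s, nrow(x$raw), length(x$truth$transient_times)
  ))
  invisible(x)
}

#' Simulate a conditioning trial schedule
#'
#' Generates trial onsets for the three session types used around appetitive
#' and aversive conditioning with an inter-trial interval drawn uniformly
#' from `iti_bounds_s` (default 75-105 s, added to the CS duration so
#' consecutive CS onsets are separated by CS + ITI):
#'
#' * `"pavlovian"`: 10 s CS with the reward US delivered 7 s after CS onset;
#' * `"fear"`: 10 s CS with a 1 s shock US at CS offset;
#' * `"stimulus"`: 10 s light-only or tone-only presentations, chosen with
#'   equal probability per trial, no US.
#'
#' @param kind `"pavlovian"`, `"fear"`, or `"stimulus"`.
#' @param n_trials number of trials (default 20 for pavlovian/stimulus, 15
#'   for fear).
#' @param seed integer seed for the ITI draws (and stimulus labels).
#' @param iti_bounds_s length-2 numeric, uniform ITI bounds in seconds.
#' @param cs_duration_s CS duration in seconds (default 10).
#' @param start_offset_s time of the first CS onset (default 60 s).
#' @return tibble with columns `trial`, `onset_s`, `label`, `cs_duration_s`,
#'   `us_offset_s` (`NA` for stimulus trials), and attributes `kind` and
#'   `iti_bounds_s`.
#' @examples
#' sched <- simulate_trial_schedule("pavlovian", n_trials = 5, seed = 3)
#' diff(sched$onset_s) # all within 85..115 s
#' @export
simulate_trial_schedule <- function(kind = c("pavlovian", "fear", "stimulus"),
                                    n_trials = NULL,
                                    seed = 1L,
                                    iti_bounds_s = c(75, 105),
                                    cs_duration_s = 10,
                                    start_offset_s = 60) {
  kind <- match.arg(kind)
  if (is.null(n_trials)) n_trials <- if (kind == "fear") 15L else 20L
  if (!is.numeric(n_trials) || n_trials < 1) abort("`n_trials` must be >= 1.")
  n_trials <- as.integer(n_trials)
  if (length(iti_bounds_s) != 2 || diff(iti_bounds_s) < 0 || any(iti_bounds_s < 0)) {
    abort("`iti_bounds_s` must be non-negative bounds (low, high).")
  }

  drawn <- with_seed(as.integer(seed), function() {
    list(
      iti = runif(max(n_trials - 1L, 0L), iti_bounds_s[1], iti_bounds_s[2]),
      stim = sample(c("LIGHT_ON", "TONE_ON"), n_trials, replace = TRUE)
    )
  })
  onsets <- start_offset_s + c(0, cumsum(cs_duration_s + drawn$iti))

  us_offset <- switch(kind,
    pavlovian = 7,
    fear = cs_duration_s,
    stimulus = NA_real_
  )
  label <- switch(kind,
    pavlovian = rep("CS_ON", n_trials),
    fear = rep("CS_ON", n_trials),
    stimulus = drawn$stim
  )

  out <- tibble(
    trial = seq_len(n_trials),
    onset_s = onsets,
    label = label,
    cs_duration_s = cs_duration_s,
    us_offset_s = us_offset
  )
  attr(out, "kind") <- kind
  attr(out, "iti_bounds_s") <- iti_bounds_s
  out
}

#' Expand a trial schedule into an event table
#'
#' Emits one `CS_ON` (or `LIGHT_ON`/`TONE_ON`) event per trial plus the
#' schedule's US marker: `PUMP` at CS onset + 7 s for pavlovian sessions
#' (the pump command; actual reward consumption is located from lick bouts),
#' `SHOCK_ON` at CS offset for fear sessions.
#'
#' @param schedule output of [simulate_trial_schedule()].
#' @return event tibble with columns `time_s`, `label`, sorted by time.
#' @export
schedule_events <- function(schedule) {
  check_columns(schedule, c("trial", "onset_s", "label"), "`schedule`")
  kind <- attr(schedule, "kind") %||% "pavlovian"
  ev <- tibble(time_s = schedule$onset_s, label = schedule$label)
  if (kind == "pavlovian") {
    ev <- dplyr::bind_rows(ev, tibble(
      time_s = schedule$onset_s + schedule$us_offset_s, label = "PUMP"
    ))
  } else if (kind == "fear") {
    ev <- dplyr::bind_rows(ev, tibble(
      time_s = schedule$onset_s + schedule$us_offset_s, label = "SHOCK_ON"
    ))
  }
  dplyr::arrange(ev, .data$time_s)
}

#' Simulate a lick train organized in bouts
#'
#' Generates lick timestamps inside each bout at the stated rate with a
#' small (10%) multiplicative jitter on the inter-lick intervals. No licks
#' are produced outside the bout windows.
#'
#' @param bouts tibble/data frame with columns `onset_s`, `rate_hz`
#'   (licks/s, > 0), and `duration_s`; bouts must not overlap.
#' @param seed integer seed.
#' @return numeric vector of sorted lick times in seconds (empty if `bouts`
#'   has no rows).
#' @examples
#' licks <- simulate_lick_train(
#'   tibble::tibble(onset_s = c(10, 20), rate_hz = 8, duration_s = 2),
#'   seed = 1
#' )
#' @export
simulate_lick_train <- function(bouts, seed = 1L) {
  check_columns(bouts, c("onset_s", "rate_hz", "duration_s"), "`bouts`")
  if (nrow(bouts) == 0) return(numeric(0))
  if (any(bouts$rate_hz <= 0)) abort("All `rate_hz` must be > 0.")
  if (any(bouts$duration_s < 0)) abort("All `duration_s` must be >= 0.")
  bouts <- dplyr::arrange(bouts, .data$onset_s)
  if (nrow(bouts) > 1) {
    ends <- bouts$onset_s + bouts$duration_s
    if (any(bouts$onset_s[-1] < ends[-nrow(bouts)])) {
      abort("Bout windows overlap; bouts must be disjoint in time.")
    }
  }
  with_seed(as.integer(seed), function() {
    licks <- purrr::pmap(bouts, function(onset_s, rate_hz, duration_s, ...) {
      n_max <- ceiling(duration_s * rate_hz) + 5
      gaps <- (1 / rate_hz) * runif(n_max, 0.9, 1.1)
      tt <- onset_s + c(0, cumsum(gaps))
      tt[tt < onset_s + duration_s]
    })
    sort(unlist(licks))
  })
}

#' Simulate a toy neuron morphology as an SWC table
#'
#' Builds minimal, exactly-known trees for validating Sholl analysis and
#' length measurements:
#'
#' * `"radial"`: a straight neurite from the soma at the origin along +x to
#'   `length_um`;
#' * `"y_branch"`: a trunk along +x to `branch_at_um`, then two straight
#'   branches at +/-45 degrees in the xy plane whose tips lie at Euclidean
#'   distance `length_um` from the soma;
#' * `"soma_only"`: a single soma node.
#'
#' Nodes are spaced `node_spacing_um` apart with the final node of each
#' branch placed exactly at the target distance.
#'
#' @param kind `"radial"`, `"y_branch"`, or `"soma_only"`.
#' @param length_um neurite length (radial) or tip distance from soma
#'   (y_branch), micrometers.
#' @param branch_at_um trunk length before the fork (y_branch only); must be
#'   smaller than `length_um`.
#' @param node_spacing_um spacing between consecutive nodes (default 1).
#' @param soma_radius_um soma node radius (default 5).
#' @return an SWC node tibble (`id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`) suitable for [sholl()] and [write_swc()].
#' @export
simulate_morphology <- function(kind = c("radial", "y_branch", "soma_only"),
                                length_um = 30,
                                branch_at_um = 12,
                                node_spacing_um = 1,
                                soma_radius_um = 5) {
  kind <- match.arg(kind)
  if (length_um < 0 || branch_at_um < 0) abort("Lengths must be non-negative.")
  soma <- tibble(
    id = 1L, type = 1L, x = 0, y = 0, z = 0,
    radius = soma_radius_um, parent = -1L
  )
  if (kind == "soma_only" || length_um == 0) return(soma)

  # distances along a straight run, spaced but ending exactly at `to`
  run_steps <- function(from, to, by) {
    s <- seq(from + by, to, by = by)
    if (length(s) == 0 || abs(s[length(s)] - to) > 1e-9) s <- c(s, to)
    s
  }

  if (kind == "radial") {
    d <- run_steps(0, length_um, node_spacing_um)
    nodes <- tibble(
      id = soma$id + seq_along(d), type = 3L,
      x = d, y = 0, z = 0, radius = 0.5,
      parent = c(soma$id, soma$id + seq_along(d)[-length(d)])
    )
    return(dplyr::bind_rows(soma, nodes))
  }

  # y_branch
  if (branch_at_um >= length_um) {
    abort("`branch_at_um` must be smaller than `length_um` for a y_branch.")
  }
  d_trunk <- run_steps(0, branch_at_um, node_spacing_um)
  trunk <- tibble(
    id = soma$id + seq_along(d_trunk), type = 3L,
    x = d_trunk, y = 0, z = 0, radius = 0.5,
    parent = c(soma$id, soma$id + seq_along(d_trunk)[-length(d_trunk)])
  )
  fork_id <- trunk$id[nrow(trunk)]
  b <- c(branch_at_um, 0)
  next_id <- fork_id
  branches <- purrr::map(c(1, -1), function(sgn) {
    dir <- c(cos(pi / 4), sgn * sin(pi / 4))
    # solve |b + t*dir| = length_um for t > 0
    bd <- sum(b * dir)
    tmax <- -bd + sqrt(bd^2 + length_um^2 - sum(b^2))
    tt <- run_steps(0, tmax, node_spacing_um)
    ids <- next_id + seq_along(tt)
    next_id <<- ids[length(ids)]
    tibble(
      id = ids, type = 3L,
      x = b[1] + tt * dir[1], y = b[2] + tt * dir[2], z = 0, radius = 0.5,
      parent = c(fork_id, ids[-length(ids)])
    )
  })
  dplyr::bind_rows(soma, trunk, branches)
}
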