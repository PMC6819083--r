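# internal validation helpers shared across modules

# check a numeric time vector for uniform spacing; returns the sampling rate.
# rel_tol is relative to the median spacing. Errors name the first offending
# index so malformed files are easy to fix.
check_uniform_time <- function(time_s, rel_tol = 1e-6, what = "time_s") {
  if (length(time_s) < 2) {
    abort(sprintf("`%s` needs at least 2 samples to define a sampling rate.", what))
  }
  dt <- diff(time_s)
  step <- median(dt)
  if (step <= 0) abort(sprintf("`%s` must be strictly increasing.", what))
  bad <- which(abs(dt - step) > rel_tol * step)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` is not uniformly spaced: first offending index %d (gap %.9g s vs median %.9g s).",
      what, bad[1] + 1L, dt[bad[1]], step
    ))
  }
  1 / step
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must have column%s %s.", what,
      if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# deterministic sub-seed derivation: one user seed fans out to independent
# component streams without reuse; kept well below .Machine$integer.max.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k)
}
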