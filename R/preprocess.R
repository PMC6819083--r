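#' Fit the isosbestic reference channel to the signal channel
#'
#' Ordinary least squares of the 490 nm signal on the 405 nm reference over
#' the whole session: `ch490 ~ slope * ch405 + intercept`. The fitted
#' reference carries the artifacts shared by both channels (motion,
#' photobleaching) scaled into signal-channel units, and is the baseline for
#' dF/F.
#'
#' @param session tibble with columns `ch490`, `ch405` (e.g. from
#'   [demodulate_session()] or [read_photometry_session()]).
#' @return an object of class `"ref_fit"`: list with `slope`, `intercept`,
#'   `fitted405` (numeric vector), and `n`. Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' sess <- tibble::tibble(
#'   time_s = 0:9 / 10,
#'   ch405 = 1 + 0.01 * (0:9), ch490 = 2 * (1 + 0.01 * (0:9)) + 3
#' )
#' fit <- fit_reference(sess)
#' tidy(fit)
#' @export
fit_reference <- function(session) {
  check_columns(session, c("ch490", "ch405"), "`session`")
  x <- session$ch405
  y <- session$ch490
  if (length(x) < 3) abort("`session` needs at least 3 samples to fit.")
  sx <- sum((x - mean(x))^2)
  if (sx <= .Machine$double.eps * length(x) * max(abs(x), 1)^2) {
    abort("`ch405` is constant; the reference fit is degenerate.")
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sx
  intercept <- mean(y) - slope * mean(x)
  structure(
    list(
      slope = slope, intercept = intercept,
      fitted405 = slope * x + intercept, n = length(x)
    ),
    class = "ref_fit"
  )
}

#' @export
print.ref_fit <- function(x, ...) {
  cat(sprintf(
    "<ref_fit> ch490 = %.6g * ch405 + %.6g  (n = %d)\n",
    x$slope, x$intercept, x$n
  ))
  invisible(x)
}

#' @method tidy ref_fit
#' @export
tidy.ref_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance ref_fit
#' @export
glance.ref_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Compute dF/F from the signal channel and the fitted reference
#'
#' `dff = (ch490 - fitted405) / fitted405`, elementwise, where `fitted405`
#' is the reference channel after the least-squares alignment of
#' [fit_reference()]. Division by the fitted reference cancels shared
#' multiplicative artifacts (bleaching) and shared fractional motion.
#'
#' @param session tibble with columns `time_s`, `ch490`, `ch405` (an `edge`
#'   column, if present, is carried through).
#' @param fit optional precomputed [fit_reference()] result; fitted values
#'   must be strictly positive at every sample.
#' @return tibble with columns `time_s`, `dff` (plus `edge` when present),
#'   with the fit stored in attribute `"ref_fit"` and the sampling rate in
#'   `"fs"`.
#' @export
compute_dff <- function(session, fit = NULL) {
  check_columns(session, c("time_s", "ch490"), "`session`")
  if (is.null(fit)) fit <- fit_reference(session)
  f405 <- fit$fitted405
  if (length(f405) != nrow(session)) {
    abort("`fit` does not match the session length.")
  }
  n_bad <- sum(f405 <= 0)
  if (n_bad > 0) {
    abort(sprintf(
      "Fitted reference is non-positive at %d sample%s; dF/F is undefined there.",
      n_bad, if (n_bad > 1) "s" else ""
    ))
  }
  out <- tibble(time_s = session$time_s, dff = (session$ch490 - f405) / f405)
  if ("edge" %in% names(session)) out$edge <- session$edge
  attr(out, "ref_fit") <- fit[c("slope", "intercept", "n")]
  attr(out, "fs") <- attr(session, "fs") %||% check_uniform_time(session$time_s)
  out
}

#' Robust z-score normalization
#'
#' `z = (x - median(x)) / MAD(x)` with `MAD = median(|x - median(x)|)`. By
#' convention no Gaussian consistency factor (1.4826) is applied, so the
#' output has median 0 and MAD exactly 1; set `consistent = TRUE` for the
#' scaled variant. The robust location/scale make the normalization
#' insensitive to sparse large transients and invariant under positive
#' affine transforms of the input.
#'
#' @param x a numeric vector, or a data frame with a `time_s` column and the
#'   trace column named by `col`.
#' @param ... passed between methods.
#' @return for vectors, a numeric vector with attributes `center` and
#'   `scale`; for data frames, a tibble with columns `time_s`, `z` (plus
#'   `dff` and `edge` when present in the input) and attributes `center`,
#'   `scale`, `fs`.
#' @examples
#' robust_z(c(1, 2, 3, 4, 100)) # median 3, MAD 1
#' @export
robust_z <- function(x, ...) UseMethod("robust_z")

#' @rdname robust_z
#' @param consistent apply the 1.4826 Gaussian consistency factor to the MAD
#'   (default `FALSE`: the literal median/MAD formula).
#' @export
robust_z.numeric <- function(x, consistent = FALSE, ...) {
  if (length(x) < 2) abort("`x` needs at least 2 samples.")
  ctr <- median(x)
  scl <- median(abs(x - ctr))
  if (consistent) scl <- scl * 1.4826
  if (scl <= 0) {
    abort("MAD of `x` is zero (constant or half-constant trace); robust z is undefined.")
  }
  structure((x - ctr) / scl, center = ctr, scale = scl)
}

#' @rdname robust_z
#' @param col name of the trace column to normalize (default `"dff"`).
#' @export
robust_z.data.frame <- function(x, col = "dff", consistent = FALSE, ...) {
  check_columns(x, c("time_s", col), "`x`")
  z <- robust_z.numeric(x[[col]], consistent = consistent)
  out <- tibble(time_s = x$time_s, z = as.numeric(z))
  if (col != "z" && col %in% names(x)) out[[col]] <- x[[col]]
  if ("edge" %in% names(x)) out$edge <- x$edge
  attr(out, "center") <- attr(z, "center")
  attr(out, "scale") <- attr(z, "scale")
  attr(out, "fs") <- attr(x, "fs") %||% check_uniform_time(x$time_s)
  out
}

#' Full trace processing: reference fit, dF/F, robust z
#'
#' Convenience pipeline chaining [fit_reference()], [compute_dff()] and
#' [robust_z()].
#'
#' @param session tibble with columns `time_s`, `ch490`, `ch405`.
#' @param consistent see [robust_z()].
#' @return tibble with columns `time_s`, `z`, `dff` (and `edge` when
#'   present), with attributes `ref_fit`, `center`, `scale`, `fs`.
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 5, seed = 1))
#' zdf <- process_session(demodulate_session(sim$raw))
#' @export
process_session <- function(session, consistent = FALSE) {
  dff <- compute_dff(session)
  out <- robust_z(dff, col = "dff", consistent = consistent)
  attr(out, "ref_fit") <- attr(dff, "ref_fit")
  out
}
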