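#' Two-sample t test from printed group summaries
#'
#' Reconstructs the unpaired two-sample t statistic from published
#' mean / SEM / n summaries, as printed in results tables. Group standard
#' deviations are recovered as `SD = SEM * sqrt(n)`. The default pooled
#' (equal-variance) form is
#' \deqn{t = \frac{\bar x_a - \bar x_b}{s_p\sqrt{1/n_a + 1/n_b}}, \quad
#'   s_p^2 = \frac{(n_a-1)SD_a^2 + (n_b-1)SD_b^2}{n_a+n_b-2}}
#' with `df = n_a + n_b - 2`; `var_equal = FALSE` gives the Welch form with
#' Satterthwaite degrees of freedom. Rounding of printed SEMs propagates
#' roughly +/-0.02 into reconstructed t values.
#'
#' @param summaries data frame with columns `label`, `mean`, `sem`, `n` and
#'   exactly two rows; the statistic is computed as row 1 minus row 2.
#' @param var_equal pooled variance (default `TRUE`) or Welch.
#' @return one-row tibble: `label_a`, `label_b`, `mean_diff`, `statistic`,
#'   `df`, `p.value` (two-sided), `method`.
#' @examples
#' t_test_summary(tibble::tibble(
#'   label = c("wt", "het"), mean = c(124.1, 171.7),
#'   sem = c(8.65, 7.779), n = c(21, 29)
#' ))
#' @export
t_test_summary <- function(summaries, var_equal = TRUE) {
  check_columns(summaries, c("label", "mean", "sem", "n"), "`summaries`")
  if (nrow(summaries) != 2) {
    abort("`summaries` must have exactly two rows (one per group).")
  }
  if (any(summaries$n < 2)) abort("Both groups need n >= 2.")
  if (any(summaries$sem < 0)) abort("SEMs must be non-negative.")
  m <- summaries$mean
  n <- summaries$n
  s <- summaries$sem * sqrt(n) # recover SDs
  if (var_equal) {
    sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / (sum(n) - 2)
    se <- sqrt(sp2 * (1 / n[1] + 1 / n[2]))
    df <- sum(n) - 2
    method <- "two-sample t (pooled, from summaries)"
  } else {
    v <- s^2 / n
    se <- sqrt(sum(v))
    df <- sum(v)^2 / sum(v^2 / (n - 1))
    method <- "Welch t (from summaries)"
  }
  stat <- (m[1] - m[2]) / se
  tibble(
    label_a = as.character(summaries$label[1]),
    label_b = as.character(summaries$label[2]),
    mean_diff = m[1] - m[2],
    statistic = stat,
    df = df,
    p.value = 2 * pt(-abs(stat), df),
    method = method
  )
}

#' Two-sample and paired t tests on raw data
#'
#' Thin tidy wrappers around [stats::t.test()] returning one-row tibbles
#' with the same columns as [t_test_summary()], so the raw-data route and
#' the summary route are directly comparable.
#'
#' @param x,y numeric vectors (for `paired_t_test`, equal length).
#' @param var_equal pooled variance (default `TRUE`) or Welch.
#' @return one-row tibble: `mean_diff`, `statistic`, `df`, `p.value`,
#'   `method`.
#' @export
t_test_raw <- function(x, y, var_equal = TRUE) {
  ht <- stats::t.test(x, y, var.equal = var_equal)
  tibble(
    mean_diff = mean(x) - mean(y),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    method = if (var_equal) "two-sample t (pooled)" else "Welch t"
  )
}

#' @rdname t_test_raw
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("Paired samples must have equal length.")
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble(
    mean_diff = mean(x - y),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    method = "paired t"
  )
}

#' @importFrom stats pt
NULL

#' Pearson correlation with R-squared
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform on `n - 2` degrees of freedom (via [stats::cor.test()]), plus
#' `r2`, the coefficient of determination reported alongside regression
#' trends.
#'
#' @param df data frame holding both variables.
#' @param x,y column names (character).
#' @return one-row tibble: `r`, `r2`, `statistic`, `df`, `p.value`.
#' @examples
#' pearson_cor(tibble::tibble(a = 1:5, b = c(2, 4, 5, 4, 5)), "a", "b")
#' @export
pearson_cor <- function(df, x, y) {
  check_columns(df, c(x, y), "`df`")
  xv <- df[[x]]
  yv <- df[[y]]
  if (length(xv) < 3) abort("`pearson_cor()` needs at least 3 observations.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Both variables need nonzero variance for a correlation.")
  }
  ht <- stats::cor.test(xv, yv, method = "pearson")
  tibble(
    r = unname(ht$estimate),
    r2 = unname(ht$estimate)^2,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled sample points of the absolute ECDF
#' difference; the p-value is the asymptotic Kolmogorov distribution (via
#' [stats::ks.test()]), the form used for large traced-cell samples.
#'
#' @param x,y numeric samples (both nonempty).
#' @return one-row tibble: `statistic` (D), `p.value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be nonempty.")
  }
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    n_x = length(x),
    n_y = length(y)
  )
}

# Benjamini-Hochberg step-up rejection at level q: reject the k smallest
# p-values where k = max{ i : p_(i) <= i q / m }.
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * q)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

#' Multiple-testing correction: Bonferroni and BKY two-stage FDR
#'
#' `method = "bonferroni"` returns adjusted p-values `min(1, m * p)` and
#' rejections at `q`. `method = "bky_two_stage"` runs the adaptive two-stage
#' linear step-up procedure of Benjamini, Krieger and Yekutieli (2006):
#' stage 1 is a BH step-up at `q' = q / (1 + q)` giving `r1` rejections and
#' the null-count estimate `m0 = m - r1`; with `r1 = 0` nothing is rejected,
#' with `m0 = 0` everything is; otherwise stage 2 is a BH step-up at level
#' `q' * m / m0`. The two-stage procedure is defined by its rejection set,
#' so it returns flags rather than adjusted p-values.
#'
#' @param p data frame with the p-value column named by `col`, or a numeric
#'   vector of p-values in `[0, 1]`.
#' @param method `"bky_two_stage"` (default) or `"bonferroni"`.
#' @param q false discovery rate / familywise level (default 0.05).
#' @param col p-value column name when `p` is a data frame (default
#'   `"p.value"`).
#' @return the input with columns `rejected` (logical) and, for Bonferroni,
#'   `p_adjusted`; a vector input returns a tibble (`p.value`, `rejected`,
#'   `p_adjusted`).
#' @examples
#' adjust_p(c(0.001, 0.01, 0.02, 0.3, 0.9), method = "bky_two_stage")
#' @export
adjust_p <- function(p, method = c("bky_two_stage", "bonferroni"),
                     q = 0.05, col = "p.value") {
  method <- match.arg(method)
  df <- if (is.data.frame(p)) {
    check_columns(p, col, "`p`")
    as_tibble(p)
  } else {
    tibble("{col}" := as.numeric(p))
  }
  pv <- df[[col]]
  if (any(is.na(pv)) || any(pv < 0 | pv > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  m <- length(pv)
  if (method == "bonferroni") {
    df$p_adjusted <- stats::p.adjust(pv, method = "bonferroni")
    df$rejected <- df$p_adjusted <= q
    return(df)
  }
  qp <- q / (1 + q)
  stage1 <- bh_reject(pv, qp)
  r1 <- sum(stage1)
  df$rejected <- if (r1 == 0) {
    rep(FALSE, m)
  } else if (r1 == m) {
    rep(TRUE, m)
  } else {
    bh_reject(pv, qp * m / (m - r1))
  }
  df
}
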