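# Independent brute-force oracles, written directly from the definitions and
# kept free of any package internals.

# peak detection oracle: enumerate plateau-start local maxima, compute
# topographic prominence by exhaustive left/right search over raw samples,
# return indices of peaks with prominence >= threshold.
oracle_detect_peaks <- function(z, threshold) {
  n <- length(z)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (z[i] > z[i - 1]) {
      j <- i + 1
      while (j <= n && z[j] == z[i]) j <- j + 1
      if (j <= n && z[j] < z[i]) peaks <- c(peaks, i)
    }
  }
  if (length(peaks) == 0) return(integer(0))
  prom <- vapply(peaks, function(i) {
    h <- z[i]
    left <- z[seq_len(i - 1)]
    higher_l <- which(left > h)
    lb <- if (length(higher_l)) min(left[max(higher_l):(i - 1)]) else min(left)
    right <- z[(i + 1):n]
    higher_r <- which(right > h)
    rb <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    h - max(lb, rb)
  }, numeric(1))
  peaks[prom >= threshold]
}

# Sholl oracle: per-radius, per-segment exhaustive straddle check
oracle_sholl_counts <- function(tree, radii) {
  root <- tree[tree$parent == -1, ]
  rc <- c(root$x, root$y, root$z)
  counts <- integer(length(radii))
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    cnt <- 0L
    for (k in seq_len(nrow(tree))) {
      pid <- tree$parent[k]
      if (pid == -1) next
      p <- tree[tree$id == pid, ]
      d1 <- sqrt(sum((c(p$x, p$y, p$z) - rc)^2))
      d2 <- sqrt(sum((c(tree$x[k], tree$y[k], tree$z[k]) - rc)^2))
      if (min(d1, d2) < r && r <= max(d1, d2)) cnt <- cnt + 1L
    }
    counts[ri] <- cnt
  }
  counts
}

# two-sample KS oracle: sup of |ECDF_x - ECDF_y| over the pooled points
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# closed-form OLS slope/intercept
oracle_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = sl, intercept = mean(y) - sl * mean(x))
}

# random small rooted tree in SWC layout
random_tree <- function(n_nodes, scale = 30) {
  tibble::tibble(
    id = seq_len(n_nodes),
    type = c(1L, rep(3L, n_nodes - 1)),
    x = c(0, runif(n_nodes - 1, -scale, scale)),
    y = c(0, runif(n_nodes - 1, -scale, scale)),
    z = c(0, runif(n_nodes - 1, -scale, scale)),
    radius = 0.5,
    parent = c(-1L, vapply(2:n_nodes, function(k) sample.int(k - 1, 1), integer(1)))
  )
}

# uniform-time trace tibble
make_trace <- function(z, fs = 100, col = "z") {
  out <- tibble::tibble(time_s = (seq_along(z) - 1) / fs)
  out[[col]] <- z
  out
}

# gaussian bump train on a zero baseline
gaussian_bumps <- function(centers_s, height, sigma_s, duration_s, fs = 382) {
  t <- seq(0, duration_s, by = 1 / fs)
  z <- rep(0, length(t))
  for (ctr in centers_s) z <- z + height * exp(-(t - ctr)^2 / (2 * sigma_s^2))
  tibble::tibble(time_s = t, z = z)
}
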