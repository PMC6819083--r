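#' Plot a processed photometry trace with detected transients
#'
#' @param x processed trace tibble with columns `time_s` and `z` (or `dff`).
#' @param transients optional `transient_table` whose peaks are marked.
#' @param col trace column to draw (default `"z"`).
#' @return a ggplot object.
#' @export
plot_trace <- function(x, transients = NULL, col = "z") {
  check_columns(x, c("time_s", col), "`x`")
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$time_s, y = .data[[col]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (s)",
      y = if (col == "z") "Robust z" else expression(Delta * F / F)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(transients) && nrow(transients) > 0) {
    p <- p + ggplot2::geom_point(
      data = transients,
      ggplot2::aes(x = .data$peak_time_s, y = .data$height_z),
      color = "firebrick", size = 1
    )
  }
  p
}

#' Heatmap of a peri-event matrix
#'
#' Trials (event order) by peri-event time, colored by session-normalized z.
#'
#' @param object a `perievent_matrix` from [extract_perievent()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot perievent_matrix
#' @export
autoplot.perievent_matrix <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$time_rel_s, y = .data$trial, fill = .data$z)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "z") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "white") +
    ggplot2::labs(
      x = sprintf("Time from %s (s)", attr(object, "label") %||% "event"),
      y = "Trial"
    ) +
    ggplot2::theme_minimal()
}

#' Trial-averaged peri-event trace
#'
#' Mean z with a standard-error ribbon across trials.
#'
#' @param mat a `perievent_matrix`.
#' @return a ggplot object.
#' @export
plot_perievent_mean <- function(mat) {
  check_columns(mat, c("trial", "time_rel_s", "z"), "`mat`")
  avg <- mat |>
    dplyr::group_by(.data$time_rel_s) |>
    dplyr::summarise(
      mean_z = mean(.data$z),
      sem_z = sd(.data$z) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_rel_s, y = .data$mean_z)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_z - .data$sem_z,
        ymax = .data$mean_z + .data$sem_z
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from event (s)", y = "z (mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' Sholl profile plot
#'
#' @param object a `sholl_profile` from [sholl()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sholl_profile
#' @export
autoplot.sholl_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$radius_um, y = .data$intersections)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Distance from soma (µm)", y = "Intersections"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
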