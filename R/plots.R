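#' Plot a velocity trace with detected darts and trial epochs
#'
#' Velocity against session time with dart events marked at their peaks and,
#' when epochs are supplied, the CS / shock-response / post-shock windows
#' shaded.
#'
#' @param trace A [velocity_trace()].
#' @param events Optional event tibble from [detect_darts()].
#' @param epochs Optional `epoch_windows` from [build_epochs()].
#' @param threshold Dart threshold reference line, cm/s (default 23.5).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, epochs = NULL, threshold = 23.5) {
  p <- ggplot2::ggplot(as_tibble(trace),
                       ggplot2::aes(x = .data$time_s, y = .data$velocity_cm_s))
  if (!is.null(epochs)) {
    shade <- as_tibble(epochs)
    shade <- shade[shade$epoch %in% c("cs", "shock_response", "post_shock"), ]
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$epoch),
      alpha = 0.2
    )
  }
  p <- p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40")
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_point(
      data = events,
      ggplot2::aes(x = .data$time_s, y = .data$peak_velocity_cm_s),
      colour = "red", size = 1
    )
  }
  p + ggplot2::labs(x = "Session time (s)", y = "Velocity (cm/s)",
                    fill = "Epoch")
}

#' Heatmap of a peri-CS dart-rate histogram
#'
#' Trials on the y axis, time relative to CS onset on the x axis, dart rate
#' (darts/min) as fill — the standard peri-stimulus view of darting around
#' the tone.
#'
#' @param object A [peri_cs_histogram()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot peri_cs_histogram
#' @export
autoplot.peri_cs_histogram <- function(object, ...) {
  bw <- attr(object, "bin_width")
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("trial", "bin", "rate")
  df$trial <- as.integer(as.character(df$trial))
  df$bin <- as.numeric(as.character(df$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin + bw / 2, y = .data$trial,
                                   fill = .data$rate)) +
    ggplot2::geom_tile(width = bw) +
    ggplot2::geom_vline(xintercept = 0, colour = "white", linetype = "dotted") +
    ggplot2::scale_y_reverse(breaks = unique(df$trial)) +
    ggplot2::labs(x = "Time from CS onset (s)", y = "Trial",
                  fill = "darts/min")
}

#' Per-trial group means of a metric across a cohort
#'
#' Convenience line plot of a per-trial metric (e.g. CS dart rate) averaged
#' within groups, mean with standard-error ribbons.
#'
#' @param data Long tibble with one row per animal-trial.
#' @param value,group,trial Column names (bare or quoted).
#' @return A ggplot object.
#' @export
plot_trial_means <- function(data, value = "value", group = "group",
                             trial = "trial") {
  value <- as_col_name(rlang::enquo(value), data)
  group <- as_col_name(rlang::enquo(group), data)
  trial <- as_col_name(rlang::enquo(trial), data)
  summ <- dplyr::summarise(
    dplyr::group_by(data, .data[[group]], .data[[trial]]),
    mean = mean(.data[[value]]),
    se = sd(.data[[value]]) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data[[trial]], y = .data$mean,
                                     colour = .data[[group]],
                                     group = .data[[group]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data[[group]]),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point()
}
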