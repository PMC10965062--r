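#' Plot keypoint trajectories
#'
#' @param object A `gait_track`.
#' @param keypoints Which keypoints to draw.
#' @param coord `"x"` or `"y"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_track <- function(object, keypoints = c("l_ankle", "r_ankle", "mid_hip"),
                                coord = c("y", "x"), ...) {
  coord <- match.arg(coord)
  df <- object[object$keypoint %in% keypoints, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[coord]],
                                   colour = .data$keypoint)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = sprintf("%s (px)", coord)) +
    ggplot2::theme_minimal()
}

#' Plot an estimated depth-change series
#'
#' @param object A `depth_series`.
#' @param events Optional [gait_events()] to mark heel-strikes.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.depth_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$delta_d)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * d ~ "(m)")) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    hs <- events[events$event == "heel_strike", ]
    p <- p + ggplot2::geom_vline(xintercept = hs$time_s, linetype = "dotted",
                                 colour = "grey50")
  }
  p
}

#' Bland-Altman plot of paired measurements
#'
#' Differences against means of the paired values, with the mean difference
#' and the 95% limits of agreement drawn as horizontal lines.
#'
#' @param x,y Paired numeric vectors (as passed to [agreement()]).
#' @param report Optional precomputed [agreement()]; recomputed if missing.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(x, y, report = NULL) {
  report <- report %||% agreement(x, y)
  df <- tibble(mean = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = report$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "mean of systems", y = "difference (A - B)") +
    ggplot2::theme_minimal()
}

#' Plot joint-angle time series
#'
#' @param object A `joint_angles` tibble.
#' @param ... Unused.
#' @return A ggplot faceted by joint, coloured by side.
#' @exportS3Method ggplot2::autoplot
autoplot.joint_angles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$angle_deg,
                                       colour = .data$side)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~joint, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}
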