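# Diagnostic plots. Each result class gets an autoplot() method so the
# usual ggplot2 idiom works: autoplot(x) + theme_bw() etc.

#' Plot a dive's time-depth profile
#'
#' High-resolution trace with, optionally, the abstracted polyline on
#' top (depth axis reversed, as is conventional for dive profiles).
#'
#' @param samples Samples tibble.
#' @param dive Dive id to plot.
#' @param profile Optional abstracted profile table containing the dive.
#' @return A ggplot object.
#' @export
plot_dive_profile <- function(samples, dive, profile = NULL) {
  s <- samples[samples$dive_id == dive, , drop = FALSE]
  if (nrow(s) == 0) abort(sprintf("dive '%s' not found in samples.", dive))
  t0 <- min(as.numeric(s$time_utc))
  df <- tibble(t_s = as.numeric(s$time_utc) - t0, depth_m = s$depth_m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$depth_m)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time in dive (s)", y = "depth (m)", title = dive)
  if (!is.null(profile)) {
    pr <- profile[profile$dive_id == dive, , drop = FALSE]
    if (nrow(pr) == 1) {
      knots <- tibble(
        t_s = c(0, pr$t1_s, pr$t2_s, pr$t3_s, pr$t4_s, pr$duration_s),
        depth_m = c(0, pr$d1_m, pr$d2_m, pr$d3_m, pr$d4_m, 0))
      p <- p +
        ggplot2::geom_line(data = knots, colour = "steelblue") +
        ggplot2::geom_point(data = knots, colour = "steelblue", size = 2)
    }
  }
  p
}

#' @export
autoplot.drift_filter_result <- function(object, binwidth = 0.02, ...) {
  ggplot2::ggplot(object$drift,
                  ggplot2::aes(x = .data$vspeed_ms)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "drift rate (m/s)", y = "fragments",
                  title = "Retained drift fragments")
}

#' @export
autoplot.r2_curve <- function(object, ...) {
  cells <- object$cells[!is.na(object$cells$r2), , drop = FALSE]
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$threshold_min),
                                      y = .data$r2)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "minimum fragment length (min)",
                  y = expression(R^2),
                  title = "Spline goodness of fit by length threshold")
}

#' @export
autoplot.drift_trend <- function(object, ...) {
  grid <- tibble(t_days = seq(object$fit_domain[1], object$fit_domain[2],
                              length.out = 200))
  grid$fit <- predict(object, grid$t_days)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$t_days, y = .data$drift_rate_ms)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "steelblue",
                       linewidth = 0.8) +
    ggplot2::labs(x = "day of record", y = "drift rate (m/s)",
                  title = sprintf("Quantile B-spline trend (tau = %.2f)",
                                  object$tau))
}

#' @export
autoplot.null_correlation <- function(object, ...) {
  ggplot2::ggplot(tibble(r = object$null_r), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey80", colour = "white") +
    ggplot2::geom_vline(xintercept = object$r_observed,
                        colour = "firebrick") +
    ggplot2::labs(x = "null correlation coefficient", y = "count",
                  title = sprintf("Observed r = %.3f, empirical P = %.4g",
                                  object$r_observed, object$p_value))
}
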