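#' Semi-log survival plot
#'
#' Viable density against time on a log axis, one line per culture —
#' the standard presentation of starvation survival curves.
#'
#' @param trajectories Tibble with `density_label`, `time_hr`, `cfu_per_ml`.
#' @param fit Optional `starve_fit` from [fit_global()]; when supplied, the
#'   fitted biphasic curves are overlaid.
#' @return A ggplot object.
#' @export
plot_survival <- function(trajectories, fit = NULL) {
  p <- ggplot2::ggplot(trajectories,
                       ggplot2::aes(x = .data$time_hr, y = .data$cfu_per_ml,
                                    colour = .data$density_label)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after growth arrest (hr)",
                  y = expression(N[CFU] ~ (cells/ml)),
                  colour = "culture")
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "starve_fit"))
    grid <- tidyr::expand_grid(
      density_label = names(fit$details$n0),
      time_hr = seq(min(trajectories$time_hr), max(trajectories$time_hr),
                    length.out = 200))
    grid$cfu_per_ml <- purrr::map2_dbl(
      grid$density_label, grid$time_hr,
      function(lbl, t) predict_cfu(fit, t, n0 = fit$details$n0[[lbl]])$cfu_per_ml)
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}

#' Log-log phase-diagnostic plot
#'
#' `log10(ln(N0/N))` against `log10(t)` with reference lines of slope 1 and
#' 2: an exponential decay falls on a slope-1 line, a Gaussian-in-time decay
#' on a slope-2 line, and biphasic kinetics bend from 2 to 1 at the
#' transition.
#'
#' @param series A [loglog_transform()] result.
#' @return A ggplot object.
#' @export
plot_loglog <- function(series) {
  mid <- c(mean(series$x), mean(series$y))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 2, intercept = mid[2] - 2 * mid[1],
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = mid[2] - mid[1],
                         linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(log[10](t / hr)),
                  y = expression(log[10](ln(N[0] / N))))
}

#' @exportS3Method ggplot2::autoplot
autoplot.starve_fit <- function(object, ...) {
  traj <- object$data
  if (!"density_label" %in% names(traj)) {
    traj$density_label <- "culture"
  }
  fit <- if (object$method == "global-constrained") object else NULL
  if (object$method == "piecewise-constrained") {
    p <- plot_survival(traj)
    grid <- tibble(time_hr = seq(min(traj$time_hr), max(traj$time_hr),
                                 length.out = 200))
    grid$cfu_per_ml <- predict_cfu(object, grid$time_hr)$cfu_per_ml
    grid$density_label <- traj$density_label[1]
    p + ggplot2::geom_line(data = grid)
  } else {
    plot_survival(traj, fit = fit)
  }
}
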