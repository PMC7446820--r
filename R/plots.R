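#' @export
autoplot.sad_ensemble <- function(object, ...) {
  p <- ggplot2::ggplot(object$summary,
                       ggplot2::aes(x = .data$index, y = .data$p_success)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$p_success - .data$se),
      ymax = pmin(1, .data$p_success + .data$se))) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(
      x = if (object$config$scenario == "generalist")
        "consumption-matrix CV" else "Cd / Co",
      y = "P(log-series fit retained)") +
    ggplot2::theme_minimal()
  if (!is.null(object$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold$threshold,
                                 linetype = 2)
  }
  p
}

#' @export
autoplot.extinction_experiment <- function(object, ...) {
  ggplot2::ggplot(object$binned,
                  ggplot2::aes(x = .data$abundance_gm, y = .data$mean_wait,
                               colour = factor(.data$index))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_wait - .data$se_wait,
      ymax = .data$mean_wait + .data$se_wait)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_wait),
                       linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "abundance (geometric bin mean)",
                  y = "mean wait to extinction (generations)",
                  colour = "index") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fluctuation_experiment <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$t, y = .data$var_D,
                               colour = factor(.data$nni))) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$var_D - .data$se, ymax = .data$var_D + .data$se,
      fill = factor(.data$nni)), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$var_D_neutral),
                       colour = "black", linetype = 2) +
    ggplot2::labs(x = "t (generations)", y = "var D(t)",
                  colour = "NNI", fill = "NNI") +
    ggplot2::theme_minimal()
}

#' Rank-abundance (SAD) plot of a trajectory's final snapshot
#'
#' @param traj A `cr_trajectory`.
#' @param ... Ignored.
#' @export
plot_sad <- function(traj, ...) {
  sad <- sort(final_sad(traj), decreasing = TRUE)
  d <- tibble::tibble(rank = seq_along(sad), abundance = sad)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$abundance)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "abundance") +
    ggplot2::theme_minimal()
}
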