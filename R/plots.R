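## ggplot2 views of the main result types.

#' Plot sweep trajectories
#'
#' Frequency trajectories of recorded mutations, optionally on a logit scale
#' (where an uninterfered deterministic sweep is a straight line).
#'
#' @param object A `sweep_sim` run with `record_trajectories = TRUE`.
#' @param logit Use a logit frequency axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_sim <- function(object, logit = TRUE, ...) {
  if (is.null(object$trajectories)) {
    abort("run with record_trajectories = TRUE to plot trajectories",
          class = "sweeprate_param_error")
  }
  p <- ggplot2::ggplot(object$trajectories,
                       ggplot2::aes(x = .data$generation, y = .data$frequency,
                                    group = .data$id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::labs(x = "generation", y = "allele frequency")
  if (logit) {
    p <- p + ggplot2::scale_y_continuous(
      trans = "logit", breaks = c(0.01, 0.1, 0.5, 0.9, 0.99))
  }
  p
}

#' Plot heterozygosity decay
#'
#' Marker heterozygosity over time for each replicate of a painting
#' experiment, on a log scale, with the neutral expectation
#' `H = H0 (1 - 1/N)^t` overlaid.
#'
#' @param object A `het_traces` object from [paint_markers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.het_traces <- function(object, ...) {
  params <- attr(object, "params")
  t0 <- attr(object, "paint_generation")
  d <- dplyr::filter(object, .data$H > 0)
  neutral <- tibble(generation = seq(t0, max(d$generation), length.out = 200))
  neutral$H <- (1 - 1 / params$N)^(neutral$generation - t0 + 1) * (1 - 1 / params$N)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$H)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate), alpha = 0.4) +
    ggplot2::geom_line(data = neutral, colour = "blue", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "marker heterozygosity")
}

#' Plot an interference kernel
#'
#' The fractional loss of fixation probability over scaled time and scaled
#' map distance caused by a single sweep.
#'
#' @param object A `kernel_grid` from [interference_kernel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kernel_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$scaled_time, y = .data$loss,
                               colour = factor(signif(.data$scaled_distance, 2)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "scaled birth time s (t - t_mid)",
                  y = "fractional loss of fixation probability",
                  colour = "r / s")
}

#' Plot theory vs baseline density
#'
#' The additive-approximation density of sweeps against the baseline
#' density, with the no-interference diagonal and the 1/(2Z) ceiling.
#'
#' @param Lambda0 Baseline densities (per Morgan per generation).
#' @param Z Interference constant.
#' @return A ggplot object.
#' @export
plot_additive_density <- function(Lambda0 = 10^seq(-2, 2, length.out = 200), Z = 1) {
  d <- tibble(Lambda0 = Lambda0, Lambda = additive_density(Lambda0, Z))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$Lambda0, y = .data$Lambda)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_hline(yintercept = 1 / (2 * Z), linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "baseline density of sweeps (per Morgan per generation)",
                  y = "density of sweeps")
}
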