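#' Plot a simulated trajectory
#'
#' Density and concentration panels against time; two-compartment
#' trajectories add the progenitor series.
#'
#' @param object A `mito_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"time",
    names_to = "variable", values_to = "value"
  )
  labs <- c(s = "stem density (cells/mm)",
            d = "progenitor density (cells/mm)",
            c = "mitogen concentration (c0 units)")
  long$variable <- factor(labs[long$variable], levels = unname(labs))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recovery fit
#'
#' Observed normalized densities (points) with the fitted model curve and
#' the homeostatic set point.
#'
#' @param object A `mito_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_fit <- function(object, ...) {
  curve <- fitted_trajectory(object)
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$time, y = .data$s_rel),
      colour = "#2166ac"
    ) +
    ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$time_days, y = .data$density)
    ) +
    ggplot2::labs(x = "days post-depletion", y = "density / steady state") +
    ggplot2::theme_minimal()
}

#' Plot the dose-response law
#'
#' @param params A [kinetic_params()].
#' @param mu Supply rates to evaluate.
#' @return A ggplot of homeostatic density against supply rate.
#' @export
plot_dose_response <- function(params, mu = seq(0.05, 0.4, by = 0.01)) {
  dr <- dose_response(params, mu)
  mu_c <- as_kinetic_params(params)$k * as_kinetic_params(params)$c0
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$mu, y = .data$s_star)) +
    ggplot2::geom_vline(xintercept = mu_c, linetype = 3) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "supply rate mu/c0 (1/day)",
                  y = "homeostatic density s* (cells/mm)") +
    ggplot2::theme_minimal()
}

#' Plot the density-versus-distance profile of a spatial run
#'
#' @param result A `spatial_result`.
#' @param sources The `source_map` used (finite positions).
#' @param bin_width Distance bin width, mm.
#' @return A ggplot of exposure-normalized density against distance to the
#'   nearest source.
#' @export
plot_density_profile <- function(result, sources, bin_width = 0.5) {
  prof <- density_vs_distance(result, sources, bin_width)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$distance, y = .data$density)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "distance to nearest source (mm)",
                  y = "mean density (cells/mm)") +
    ggplot2::theme_minimal()
}
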