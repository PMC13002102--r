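#' Plot the unconditioned and conditioned expectation curves
#'
#' Visualizes the tension at the heart of the model: averaged over all
#' perturbations the fitness effect of noise falls as `-sigma^2`, while
#' averaged over beneficial perturbations only it rises toward a plateau of
#' `(2/3) z0^2` — higher for organisms further from the optimum.
#'
#' @param object A `"dfe_curves"` tibble from [dfe_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dfe_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("expected_effect", "conditional_expected_effect"),
    names_to = "average", values_to = "value"
  )
  long$average <- factor(long$average,
                         levels = c("expected_effect", "conditional_expected_effect"),
                         labels = c("over all phenotypes", "over beneficial phenotypes"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sigma, y = .data$value,
                                     colour = .data$average,
                                     linetype = factor(abs(.data$z0)))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = expression(sigma[phenotype]),
                  y = "expected fitness effect",
                  colour = "averaged", linetype = "|z0|") +
    ggplot2::theme_minimal()
}

#' Plot phenotype and fitness-effect densities
#'
#' @param object A tibble from [dfe_density_table()].
#' @param ... Unused.
#' @return A ggplot, densities faceted by variable with one curve per
#'   `(z0, sigma)`.
#' @export
plot_dfe_density <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$density,
                               colour = interaction(.data$z0, .data$sigma, sep = ", "))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$variable, scales = "free") +
    ggplot2::labs(colour = "z0, sigma") +
    ggplot2::theme_minimal()
}

#' Plot a parameter scan
#'
#' Fixation probability of the high-noise allele across the scanned
#' parameter (noise magnitude or population size) with 3-SE error bars and
#' the neutral expectation for reference.
#'
#' @param object A `"noise_scan"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noise_scan <- function(object, ...) {
  xvar <- if (identical(attr(object, "scan_type"), "sigma")) "sigma" else "pop_size"
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data[[xvar]], y = .data$fixation_prob_high)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$fixation_prob_high - 3 * .data$se),
                                          ymax = pmin(1, .data$fixation_prob_high + 3 * .data$se))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$neutral_expectation), linetype = "dashed") +
    ggplot2::labs(y = "fixation probability of the high-noise allele",
                  x = if (xvar == "sigma") expression(sigma[invader]) else "population size N") +
    ggplot2::theme_minimal()
  if (xvar == "pop_size") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a fixation trajectory
#'
#' @param object A `"wf_run"` with a stored trajectory.
#' @param ... Unused.
#' @return A ggplot of the high-allele frequency over generations.
#' @export
autoplot.wf_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$freq_high)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "frequency of the high-noise allele") +
    ggplot2::theme_minimal()
}
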