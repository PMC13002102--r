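#' Monte-Carlo estimate of the mean fitness effect
#'
#' Brute-force check of the closed form `-sigma^2`: draws phenotypes from
#' the noise distribution, pushes them through the fitness map, and averages.
#' This sampling path shares no transformation code with the analytic
#' density [dfe_pdf()], so agreement between the two is a genuine
#' cross-validation.
#'
#' @inheritParams sample_phenotypes
#' @param n Number of draws (at least 1000 for a meaningful standard error).
#' @return One-row tibble of class `"mc_estimate"`: `value`, `std_error`
#'   (sample sd / sqrt(n)), `n`, `seed`.
#' @examples
#' mc_expected_effect(-2, 0.4, n = 1e5, seed = 1)
#' @export
mc_expected_effect <- function(z0, sigma, n = 1e6, seed = NULL,
                               dist = c("normal", "uniform", "laplace")) {
  stopifnot(n >= 1e3)
  dist <- match.arg(dist)
  z <- sample_phenotypes(z0, sigma, n, seed = seed, dist = dist)
  dr <- fitness_effect(z, z0)
  out <- tibble(
    value = mean(dr),
    std_error = if (sigma == 0) 0 else sd(dr) / sqrt(n),
    n = as.integer(n),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  class(out) <- c("mc_estimate", class(out))
  out
}

#' Numerical moments of the fitness-effect density
#'
#' Adaptive quadrature of `delta_r^order * f(delta_r)` against the
#' change-of-variable density [dfe_pdf()], over the full support or
#' restricted to the beneficial part `(0, z0^2]`. The upper limit is the
#' (open) singular boundary `z0^2`; the lower limit is truncated where the
#' phenotype is 10 standard deviations from its mean, beyond which the
#' neglected mass is far below the integration tolerance. The order-0
#' unrestricted moment is a normalization check (should be 1); the ratio of
#' the restricted first to the restricted zeroth moment is the quadrature
#' reference for [conditional_expected_effect()].
#'
#' @inheritParams dfe_pdf
#' @param order Moment order, 0 or 1.
#' @param restrict_beneficial If `TRUE`, integrate over `(0, z0^2]` only.
#' @param abs_tol Absolute quadrature tolerance.
#' @return Scalar value of the integral.
#' @examples
#' quad_moment(-2, 0.4, order = 0)                             # ~ 1
#' quad_moment(-2, 0.4, order = 1)                             # ~ -0.16
#' quad_moment(-2, 0.4, 1, TRUE) / quad_moment(-2, 0.4, 0, TRUE)
#' @export
quad_moment <- function(z0, sigma, order = 0, restrict_beneficial = FALSE,
                        abs_tol = 1e-9) {
  stopifnot(is.numeric(z0), length(z0) == 1, order %in% c(0, 1))
  check_sigma(sigma)
  if (sigma == 0) abort("`sigma` = 0 is degenerate: no density to integrate.")
  if (restrict_beneficial && z0 == 0) return(0) # empty beneficial set
  z_far <- max(abs(z0 - 10 * sigma), abs(z0 + 10 * sigma))
  lower <- if (restrict_beneficial) 0 else z0^2 - z_far^2
  res <- tryCatch(
    integrate(function(d) d^order * dfe_pdf(d, z0, sigma),
              lower = lower, upper = z0^2,
              rel.tol = abs_tol, abs.tol = abs_tol,
              subdivisions = 2000L, stop.on.error = TRUE),
    error = function(e) abort(paste0("quadrature of the fitness-effect density failed: ",
                                     conditionMessage(e)))
  )
  res$value
}

# Quantile of the fitness-effect distribution, by root-finding on its CDF
# P(dr <= x) = 1 - P(|Z| < sqrt(z0^2 - x)).
dfe_quantile <- function(p, z0, sigma) {
  stopifnot(p > 0, p < 1)
  cdf <- function(x) {
    s <- sqrt(z0^2 - x)
    1 - (pnorm((s - z0) / sigma) - pnorm((-s - z0) / sigma))
  }
  z_far <- max(abs(z0 - 12 * sigma), abs(z0 + 12 * sigma))
  lo <- z0^2 - z_far^2
  hi <- z0^2 - .Machine$double.eps * max(1, z0^2)
  uniroot(function(x) cdf(x) - p, lower = lo, upper = hi, tol = 1e-12)$root
}

#' Compare sampled fitness effects with the analytic density
#'
#' Bins `n` Monte-Carlo fitness effects (phenotype draws pushed through the
#' fitness map) into equal-probability bins of the analytic density and
#' compares observed with expected bin masses. Equal-probability binning
#' keeps the boundary singularity from concentrating in one bin. The check
#' passes when every bin's deviation is within 3 binomial standard errors
#' of its expected mass `1/bins`.
#'
#' `densities_from` deliberately allows a mismatched density model — a
#' negative control that the check can fail.
#'
#' @inheritParams mc_expected_effect
#' @param bins Number of equal-probability bins.
#' @param densities_from Optional list with elements `z0`, `sigma` giving the
#'   model whose density is binned against; defaults to the sampling model.
#' @return List of class `"dfe_check"`: `table` (per-bin tibble), `max_abs_dev`
#'   (max |observed - expected| mass), `max_se_units`, `pass`, `n`, `bins`.
#' @examples
#' empirical_dfe_check(-2, 0.4, n = 1e5, bins = 20, seed = 1)$pass
#' @export
empirical_dfe_check <- function(z0, sigma, n = 1e6, bins = 50, seed = NULL,
                                densities_from = NULL) {
  stopifnot(n >= 1e4, bins >= 2)
  check_sigma(sigma)
  if (sigma == 0) abort("`sigma` = 0 is degenerate: nothing to check.")
  dm <- densities_from %||% list(z0 = z0, sigma = sigma)
  probs <- seq_len(bins - 1) / bins
  edges <- c(-Inf, vapply(probs, dfe_quantile, numeric(1),
                          z0 = dm$z0, sigma = dm$sigma), dm$z0^2)
  dr <- fitness_effect(sample_phenotypes(z0, sigma, n, seed = seed), z0)
  counts <- table(cut(dr, breaks = edges, include.lowest = TRUE))
  observed <- as.numeric(counts) / n
  expected <- rep(1 / bins, bins)
  se <- sqrt(expected * (1 - expected) / n)
  tab <- tibble(
    bin = seq_len(bins),
    lower = edges[-length(edges)],
    upper = edges[-1],
    observed = observed,
    expected = expected,
    se_units = (observed - expected) / se
  )
  structure(list(
    table = tab,
    max_abs_dev = max(abs(observed - expected)),
    max_se_units = max(abs(tab$se_units)),
    pass = all(abs(tab$se_units) <= 3),
    n = as.integer(n), bins = as.integer(bins)
  ), class = "dfe_check")
}

#' @export
print.dfe_check <- function(x, ...) {
  cat("Empirical check of the fitness-effect density\n")
  cat(sprintf("  %d draws in %d equal-probability bins\n", x$n, x$bins))
  cat(sprintf("  max |observed - expected| mass: %.2e (%.2f SE)\n",
              x$max_abs_dev, x$max_se_units))
  cat(sprintf("  pass (all bins within 3 SE): %s\n", x$pass))
  invisible(x)
}

#' Run the closed-form verification suite
#'
#' Executes every analytic-versus-oracle check the package makes:
#' normalization of the fitness-effect density, the `-sigma^2` unconditioned
#' mean against quadrature, the conditioned mean against the quadrature
#' moment ratio, and (optionally) the neutral 1/N calibration of the
#' Wright-Fisher engine. `fault_eq5` perturbs the conditioned closed form
#' multiplicatively — a documented hook for negative-control testing of this
#' very suite.
#'
#' @param grid Data frame of `(z0, sigma)` points to check; defaults to the
#'   standard 12-point grid.
#' @param fault_eq5 Relative perturbation injected into the conditioned
#'   closed form before comparison (0 = none).
#' @param include_neutral Also run the neutral-calibration simulation check.
#' @param replicates Replicates for the neutral check.
#' @param seed Seed for the neutral check.
#' @return Tibble of class `"verify_report"` with columns `check`, `value`,
#'   `reference`, `tolerance`, `pass`; attribute `pass` is the conjunction.
#' @examples
#' verify_closed_forms(include_neutral = FALSE)
#' @export
verify_closed_forms <- function(grid = NULL, fault_eq5 = 0,
                                include_neutral = TRUE,
                                replicates = 2000, seed = 1) {
  grid <- grid %||% tidyr::expand_grid(z0 = c(-2, -1, -0.1),
                                       sigma = c(0.05, 0.4, 1, 4))
  rows <- purrr::pmap_dfr(grid, function(z0, sigma) {
    norm <- quad_moment(z0, sigma, 0)
    m1 <- quad_moment(z0, sigma, 1)
    cond_q <- quad_moment(z0, sigma, 1, TRUE) / quad_moment(z0, sigma, 0, TRUE)
    cond_c <- conditional_expected_effect(z0, sigma) * (1 + fault_eq5)
    lab <- sprintf("(z0 = %g, sigma = %g)", z0, sigma)
    tibble(
      check = c(paste("density normalization", lab),
                paste("unconditioned mean vs quadrature", lab),
                paste("conditioned mean vs quadrature", lab)),
      value = c(norm, -sigma^2, cond_c),
      reference = c(1, m1, cond_q),
      tolerance = c(1e-6, 1e-6, 1e-4),
      relative = c(FALSE, FALSE, TRUE)
    )
  })
  if (include_neutral) {
    cfg <- sim_config(pop_size = 20, sigma_low = 0.4, sigma_high = 0.4,
                      init_freq_high = 1 / 20)
    fp <- fixation_probability(cfg, replicates = replicates, seed = seed)
    rows <- dplyr::bind_rows(rows, tibble(
      check = sprintf("neutral single-invader fixation vs 1/N (N = 20, %d replicates)",
                      replicates),
      value = fp$fixation_prob_high,
      reference = 1 / 20,
      tolerance = 3 * sqrt((1 / 20) * (19 / 20) / replicates),
      relative = FALSE
    ))
  }
  dev <- abs(rows$value - rows$reference)
  rows$pass <- ifelse(rows$relative, dev / abs(rows$reference) <= rows$tolerance,
                      dev <= rows$tolerance)
  class(rows) <- c("verify_report", class(rows))
  attr(rows, "pass") <- all(rows$pass)
  rows
}
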