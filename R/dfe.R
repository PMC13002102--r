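#' Quadratic Malthusian fitness map
#'
#' Malthusian (log-scale, continuous-time) fitness drops quadratically with
#' the distance between the realized phenotype and the phenotypic optimum:
#' `r(z) = r_optimum - (z_optimum - z)^2`. The optimum is the unique maximum,
#' so every perturbation away from it is deleterious in absolute fitness.
#'
#' @param z Numeric vector of realized phenotypes (trait units).
#' @param z_optimum Position of the phenotypic optimum. Default 0.
#' @param r_optimum Malthusian fitness at the optimum. Default 0; it shifts
#'   all fitnesses additively and cancels from every fitness *effect*.
#'
#' @return Numeric vector of Malthusian fitnesses, same length as `z`.
#' @examples
#' malthusian_fitness(0, r_optimum = 1)   # 1, at the optimum
#' malthusian_fitness(-2, r_optimum = 5)  # 5 - 4 = 1
#' @export
malthusian_fitness <- function(z, z_optimum = 0, r_optimum = 0) {
  stopifnot(is.numeric(z), is.numeric(z_optimum), is.numeric(r_optimum))
  r_optimum - (z_optimum - z)^2
}

#' Fitness effect of a phenotypic perturbation
#'
#' The fitness effect of realizing phenotype `z` in an organism whose
#' expected phenotype is `z0` is `r(z) - r(z0)`. Under the quadratic map
#' this is `z0^2 - z^2` when the optimum sits at the origin; a general
#' `z_optimum` is handled by translating coordinates, and `r_optimum`
#' cancels entirely.
#'
#' @param z Numeric vector of realized phenotypes.
#' @param z0 Expected phenotype of the organism (trait units).
#' @param z_optimum Position of the phenotypic optimum. Default 0.
#'
#' @return Numeric vector of fitness effects (Malthusian units). Positive
#'   values are beneficial perturbations; the supremum is `(z0 - z_optimum)^2`,
#'   attained as `z` reaches the optimum.
#' @examples
#' fitness_effect(0, z0 = -2)   # 4: jumping to the optimum
#' fitness_effect(-5, z0 = -2)  # -21
#' @export
fitness_effect <- function(z, z0, z_optimum = 0) {
  stopifnot(is.numeric(z), is.numeric(z0), is.numeric(z_optimum))
  (z0 - z_optimum)^2 - (z - z_optimum)^2
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || any(is.na(sigma)) || any(sigma < 0)) {
    abort("`sigma` must be a non-negative number (noise magnitude).")
  }
  invisible(sigma)
}

#' Draw noisy phenotypes
#'
#' Samples realized phenotypes for an organism with expected phenotype `z0`
#' and noise magnitude `sigma`. The default is the model's Gaussian noise,
#' `Z ~ N(z0, sigma^2)`; uniform and Laplace alternatives with the *same
#' variance* are provided to exercise the distribution-free property of the
#' unconditioned expected fitness effect (it is `-sigma^2` for any noise
#' density with variance `sigma^2`).
#'
#' @param z0 Expected phenotype.
#' @param sigma Noise magnitude (standard deviation of the perturbation);
#'   `sigma = 0` gives the degenerate point mass at `z0`.
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied the draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @param dist Noise family: `"normal"` (the model), or variance-matched
#'   `"uniform"` / `"laplace"`.
#'
#' @return Numeric vector of `n` phenotypes.
#' @examples
#' sample_phenotypes(-2, 0, 3)               # c(-2, -2, -2)
#' sample_phenotypes(-2, 0.4, 5, seed = 1)
#' @export
sample_phenotypes <- function(z0, sigma, n,
                              seed = NULL,
                              dist = c("normal", "uniform", "laplace")) {
  stopifnot(is.numeric(z0), length(z0) == 1, is.numeric(n), n >= 1)
  check_sigma(sigma)
  dist <- match.arg(dist)
  n <- as.integer(n)
  draw <- function() {
    if (sigma == 0) return(rep(z0, n))
    switch(dist,
      normal  = rnorm(n, mean = z0, sd = sigma),
      # half-width sqrt(3)*sigma gives variance sigma^2
      uniform = z0 + runif(n, -sqrt(3) * sigma, sqrt(3) * sigma),
      # difference of two exponentials with scale sigma/sqrt(2): Laplace,
      # variance 2 * (sigma/sqrt(2))^2 = sigma^2
      laplace = z0 + (rexp(n) - rexp(n)) * sigma / sqrt(2)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Density of the distribution of fitness effects
#'
#' Change-of-variable density of the fitness effect `dr = z0^2 - z^2` induced
#' by Gaussian phenotypic noise `Z ~ N(z0, sigma^2)` (optimum at the origin).
#' For `dr < z0^2` the two phenotypes `z = +/- sqrt(z0^2 - dr)` map to the
#' same effect, so
#' \deqn{f(\Delta r) = \frac{\phi(s; z_0, \sigma) + \phi(-s; z_0, \sigma)}
#'   {2 s}, \quad s = \sqrt{z_0^2 - \Delta r},}
#' where \eqn{\phi} is the Gaussian density. The support is
#' `(-Inf, z0^2]`; the density diverges at the upper endpoint `dr = z0^2`
#' (an integrable, square-root singularity), so evaluation exactly there is
#' an error rather than a finite number — integrate with an open upper limit.
#'
#' @param delta_r Numeric vector of fitness effects at which to evaluate.
#' @param z0 Expected phenotype.
#' @param sigma Noise magnitude; must be strictly positive (the `sigma = 0`
#'   point mass has no density).
#'
#' @return Numeric vector of densities; 0 outside the support
#'   (`delta_r > z0^2`).
#' @examples
#' dfe_pdf(c(-1, 0, 3.9), z0 = -2, sigma = 0.4)
#' dfe_pdf(5, z0 = -2, sigma = 0.4)  # 0, outside the support
#' @export
dfe_pdf <- function(delta_r, z0, sigma) {
  stopifnot(is.numeric(delta_r), is.numeric(z0), length(z0) == 1)
  check_sigma(sigma)
  if (sigma == 0) {
    abort("`sigma` = 0 is degenerate: the fitness-effect distribution is a point mass with no density.")
  }
  if (any(delta_r == z0^2)) {
    abort(paste0(
      "dfe_pdf() has an integrable singularity at the boundary delta_r = z0^2 = ",
      format(z0^2), "; evaluate strictly inside the support."
    ))
  }
  out <- numeric(length(delta_r))
  inside <- delta_r < z0^2
  s <- sqrt(z0^2 - delta_r[inside])
  out[inside] <- (dnorm(s, mean = z0, sd = sigma) +
                    dnorm(-s, mean = z0, sd = sigma)) / (2 * s)
  out
}

#' Unconditioned expected fitness effect of noise
#'
#' The mean fitness effect of a phenotypic perturbation, averaged over all
#' realizations, is exactly `-sigma^2`: since `E[dr] = E[z0^2 - Z^2] =
#' z0^2 - (Var(Z) + z0^2) = -Var(Z)`, the result does not depend on `z0`
#' nor on the shape of the noise density — only on its variance. Noise is
#' therefore deleterious on average (Jensen's inequality on a concave-down
#' fitness map), without limit as `sigma` grows.
#'
#' @param sigma Noise magnitude (vectorized).
#' @return `-sigma^2`.
#' @examples
#' expected_effect(0.4)  # -0.16, for any z0 and any noise shape
#' @export
expected_effect <- function(sigma) {
  check_sigma(sigma)
  -sigma^2
}

# Standardized endpoints of the beneficial phenotype interval (-|z0|, |z0|).
beneficial_endpoints <- function(z0, sigma) {
  a <- abs(z0)
  list(lo = (-a - z0) / sigma, hi = (a - z0) / sigma)
}

#' Probability that a phenotypic perturbation is beneficial
#'
#' A perturbation is beneficial iff the realized phenotype lands closer to
#' the optimum than the expected phenotype: `P(dr > 0) = P(|Z| < |z0|)`.
#' At the optimum (`z0 = 0`) every perturbation is deleterious, so the
#' probability is 0; as `sigma -> 0` with `z0 != 0` it approaches 1/2
#' (half of vanishingly small symmetric perturbations point toward the
#' optimum).
#'
#' @inheritParams dfe_pdf
#' @return Probability in `[0, 1]`. `sigma = 0` returns 0 (the point mass
#'   sits at `z0`, where the effect is exactly zero, not positive).
#' @examples
#' beneficial_probability(z0 = 0, sigma = 0.4)    # 0
#' beneficial_probability(z0 = -2, sigma = 1e-6)  # ~ 0.5
#' @export
beneficial_probability <- function(z0, sigma) {
  stopifnot(is.numeric(z0), length(z0) == 1)
  check_sigma(sigma)
  if (sigma == 0 || z0 == 0) return(0)
  ep <- beneficial_endpoints(z0, sigma)
  pnorm(ep$hi) - pnorm(ep$lo)
}

#' Expected fitness effect conditioned on a beneficial outcome
#'
#' Mean fitness effect among the perturbations that improve fitness,
#' `E[dr | dr > 0]`. Evaluated in closed form from truncated Gaussian
#' moments over the beneficial phenotype interval `(-|z0|, |z0|)`:
#' with standardized endpoints \eqn{\alpha, \beta} and
#' \eqn{I_0 = \Phi(\beta) - \Phi(\alpha)},
#' \deqn{E[\Delta r \mid \Delta r > 0] =
#'   \frac{-2 z_0 \sigma (\phi(\alpha) - \phi(\beta))
#'         - \sigma^2 (I_0 + \alpha\phi(\alpha) - \beta\phi(\beta))}{I_0}.}
#' The value is always positive, rises with `sigma` toward a plateau of
#' `(2/3) z0^2` (for the reference parameterization `|z0| = 2` it is
#' monotone on `sigma` in `[0.05, 2]`; for small `|z0|` the curve slightly
#' overshoots the plateau at large `sigma` before settling onto it), and the
#' plateau grows with the distance `|z0|` from the optimum. Agreement with
#' direct quadrature of the fitness-effect density is the package's
#' authoritative check (see [quad_moment()]).
#'
#' @inheritParams dfe_pdf
#' @return Positive scalar, `E[dr | dr > 0]`.
#' @examples
#' conditional_expected_effect(z0 = -2, sigma = 0.4)
#' conditional_expected_effect(z0 = -2, sigma = 1e3)  # ~ (2/3) * 4
#' @export
conditional_expected_effect <- function(z0, sigma) {
  stopifnot(is.numeric(z0), length(z0) == 1)
  check_sigma(sigma)
  if (z0 == 0) {
    abort(paste(
      "All phenotypic perturbations are deleterious if an organism's expected",
      "phenotype is at the fitness optimum (z0 = 0): conditioning on a",
      "beneficial outcome is conditioning on a null event."
    ))
  }
  if (sigma == 0) {
    abort("`sigma` = 0 is degenerate: no perturbations occur, so no beneficial ones exist.")
  }
  ep <- beneficial_endpoints(z0, sigma)
  i0 <- pnorm(ep$hi) - pnorm(ep$lo)
  ex1 <- dnorm(ep$lo) - dnorm(ep$hi)                     # E[X 1{A}], X std normal
  ex2 <- i0 + ep$lo * dnorm(ep$lo) - ep$hi * dnorm(ep$hi) # E[X^2 1{A}]
  (-2 * z0 * sigma * ex1 - sigma^2 * ex2) / i0
}

#' Summarize the fitness-effect distribution over a parameter table
#'
#' Data-frame-first entry point: takes one `(z0, sigma)` pair per row and
#' returns the row-wise summary of the induced distribution of fitness
#' effects — the unconditioned mean `-sigma^2`, the probability that a
#' perturbation is beneficial, the mean effect conditioned on a beneficial
#' outcome (`NA` where no beneficial outcomes exist), and the maximal
#' attainable effect `z0^2`.
#'
#' @param params Data frame with numeric columns `z0` and `sigma`.
#' @return A tibble with the input columns plus `expected_effect`,
#'   `p_beneficial`, `conditional_expected_effect`, `max_effect`.
#' @examples
#' dfe_summary(data.frame(z0 = c(-2, -2, 0), sigma = c(0.4, 0.05, 0.4)))
#' @export
dfe_summary <- function(params) {
  if (!is.data.frame(params) || !all(c("z0", "sigma") %in% names(params))) {
    abort("`params` must be a data frame with columns `z0` and `sigma`.")
  }
  out <- tibble::as_tibble(params)
  out$expected_effect <- expected_effect(out$sigma)
  out$p_beneficial <- purrr::map2_dbl(out$z0, out$sigma, beneficial_probability)
  out$conditional_expected_effect <- purrr::map2_dbl(
    out$z0, out$sigma,
    function(z0, s) if (z0 == 0 || s == 0) NA_real_ else conditional_expected_effect(z0, s)
  )
  out$max_effect <- out$z0^2
  class(out) <- c("dfe_summary", class(out))
  out
}

#' Tabulate model densities and expectation curves
#'
#' `dfe_density_table()` evaluates the phenotype density and the induced
#' fitness-effect density on grids, for plotting or export. `dfe_curves()`
#' traces the unconditioned (`-sigma^2`) and beneficial-conditioned
#' expectations as functions of the noise magnitude, one pair of curves per
#' expected phenotype.
#'
#' @param z0 Expected phenotype(s); `dfe_density_table()` takes one value
#'   per `sigma` via recycling, `dfe_curves()` one curve pair per element.
#' @param sigma Noise magnitude(s), strictly positive.
#' @param n_grid Number of grid points per density.
#' @param sigma_grid Numeric vector of noise magnitudes for `dfe_curves()`.
#'
#' @return A tibble. For `dfe_density_table()`: columns `z0`, `sigma`,
#'   `variable` (`"phenotype"` or `"fitness_effect"`), `x`, `density`; the
#'   fitness-effect grid stops just short of the boundary singularity at
#'   `z0^2`. For `dfe_curves()`: columns `z0`, `sigma`, `expected_effect`,
#'   `conditional_expected_effect` (class `"dfe_curves"`).
#' @examples
#' dfe_density_table(z0 = -2, sigma = c(0.4, 0.05), n_grid = 101)
#' dfe_curves(z0 = c(-2, -1), sigma_grid = seq(0.05, 2, by = 0.05))
#' @export
dfe_density_table <- function(z0, sigma, n_grid = 512) {
  stopifnot(is.numeric(z0), is.numeric(sigma), n_grid >= 2)
  check_sigma(sigma)
  if (any(sigma == 0)) abort("densities require `sigma` > 0.")
  pairs <- tibble(z0 = z0, sigma = sigma) # recycles scalar z0
  purrr::pmap_dfr(pairs, function(z0, sigma) {
    zg <- seq(z0 - 4 * sigma, z0 + 4 * sigma, length.out = n_grid)
    lo <- z0^2 - (abs(z0) + 4 * sigma)^2
    hi <- z0^2 - (z0^2 - lo) * 1e-6 # open at the singular boundary
    dg <- seq(lo, hi, length.out = n_grid)
    dens_z <- dnorm(zg, z0, sigma)
    dens_d <- dfe_pdf(dg, z0, sigma)
    dplyr::bind_rows(
      tibble(z0 = z0, sigma = sigma, variable = "phenotype",
             x = zg, density = dens_z),
      tibble(z0 = z0, sigma = sigma, variable = "fitness_effect",
             x = dg, density = dens_d)
    )
  })
}

#' @rdname dfe_density_table
#' @export
dfe_curves <- function(z0, sigma_grid) {
  stopifnot(is.numeric(z0), is.numeric(sigma_grid), length(sigma_grid) >= 1)
  check_sigma(sigma_grid)
  out <- tidyr::expand_grid(z0 = z0, sigma = sigma_grid)
  out <- dfe_summary(out)[, c("z0", "sigma", "expected_effect",
                              "conditional_expected_effect")]
  class(out) <- c("dfe_curves", class(out))
  out
}

#' Largest beneficial perturbation magnitude, by brute-force scan
#'
#' Under the quadratic map, a perturbation `delta = z - z0` is beneficial
#' iff it moves the phenotype strictly inside `(-|z0|, |z0|)`; every
#' perturbation of magnitude larger than `2|z0|` is deleterious regardless
#' of sign. This function establishes that bound empirically, by scanning a
#' fine grid of magnitudes and checking both signs, rather than by algebra —
#' it is a verification device.
#'
#' @param z0 Expected phenotype, nonzero.
#' @param step Grid resolution in trait units.
#' @param max_mult Scan magnitudes up to `max_mult * |z0|`.
#' @return A list: `sup_beneficial` (largest scanned magnitude that is
#'   beneficial for at least one sign), `multiple_of_z0`
#'   (`sup_beneficial / |z0|`, which approaches 2 as `step -> 0`), and
#'   `n_scanned`.
#' @examples
#' beneficial_magnitude_bound(-2, step = 1e-4)$multiple_of_z0  # ~ 2
#' @export
beneficial_magnitude_bound <- function(z0, step = 1e-6, max_mult = 3) {
  stopifnot(is.numeric(z0), length(z0) == 1, z0 != 0, step > 0)
  m <- seq(0, max_mult * abs(z0), by = step)
  beneficial <- fitness_effect(z0 + m, z0) > 0 | fitness_effect(z0 - m, z0) > 0
  sup <- max(m[beneficial])
  list(sup_beneficial = sup,
       multiple_of_z0 = sup / abs(z0),
       n_scanned = length(m))
}
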