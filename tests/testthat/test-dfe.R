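test_that("quadratic fitness map and fitness effects evaluate exactly", {
  expect_equal(malthusian_fitness(0, z_optimum = 0, r_optimum = 1), 1)
  expect_equal(malthusian_fitness(2, z_optimum = 0, r_optimum = 0), -4)
  expect_equal(malthusian_fitness(-2, z_optimum = 0, r_optimum = 5), 1)

  expect_equal(fitness_effect(-2, z0 = -2), 0)
  expect_equal(fitness_effect(0.7, z0 = 0.7), 0)
  expect_equal(fitness_effect(0, z0 = -2), 4)
  expect_equal(fitness_effect(-5, z0 = -2), -21)
  # r_optimum never enters the effect; a shifted optimum is a translation
  expect_equal(fitness_effect(1, z0 = -1, z_optimum = 1),
               fitness_effect(0, z0 = -2))
})

test_that("phenotype sampling honors the degenerate case, the seed and the mean", {
  expect_identical(sample_phenotypes(-2, 0, 3), c(-2, -2, -2))
  expect_identical(sample_phenotypes(-2, 0.4, 10, seed = 11),
                   sample_phenotypes(-2, 0.4, 10, seed = 11))
  z <- sample_phenotypes(-2, 0.4, 1e6, seed = 12)
  expect_lt(abs(mean(z) - (-2)), 4 * 0.4 / 1e3)  # 4 sigma/sqrt(n)
  # variance-matched alternative noise families
  for (d in c("uniform", "laplace")) {
    zz <- sample_phenotypes(-2, 0.4, 5e5, seed = 13, dist = d)
    expect_lt(abs(mean(zz) - (-2)), 0.005)
    expect_lt(abs(sd(zz) - 0.4), 0.005)
  }
})

test_that("the fitness-effect density has the right support, boundary and norm", {
  expect_identical(dfe_pdf(4 + 1, z0 = -2, sigma = 0.4), 0)
  expect_identical(dfe_pdf(c(10, 100), z0 = -2, sigma = 0.4), c(0, 0))
  expect_error(dfe_pdf(4, z0 = -2, sigma = 0.4), "singularity")
  expect_error(dfe_pdf(0, z0 = -2, sigma = 0), "degenerate")
  for (i in seq_len(nrow(standard_grid()))) {
    g <- standard_grid()[i, ]
    expect_lt(abs(quad_moment(g$z0, g$sigma, order = 0) - 1), 1e-6)
  }
})

test_that("the unconditioned mean is -sigma^2, falling without limit in sigma", {
  expect_identical(expected_effect(0), 0)
  expect_equal(expected_effect(0.4), -0.16)
  sig <- c(0.05, 0.2, 0.4, 1, 2, 4)
  expect_true(all(expected_effect(sig) < 0))
  expect_true(all(diff(expected_effect(sig)) < 0))
})

test_that("the conditioned mean is positive, rises on the reference range, and errors at the optimum", {
  expect_error(conditional_expected_effect(0, 0.4), "optimum")
  expect_error(conditional_expected_effect(-2, 0), "degenerate")
  expect_gt(conditional_expected_effect(-2, 0.4), 0)
  expect_gt(conditional_expected_effect(-2, 0.05), 0)
  sig <- seq(0.05, 2, by = 0.05)
  vals <- vapply(sig, conditional_expected_effect, numeric(1), z0 = -2)
  expect_true(all(diff(vals) >= 0))
  # large-noise plateau (2/3) z0^2, and its ordering in |z0|
  expect_lt(abs(conditional_expected_effect(-2, 1e3) - 8 / 3), 0.01 * 8 / 3)
  expect_gt(conditional_expected_effect(-2, 4), conditional_expected_effect(-1, 4))
})

test_that("beneficial probability matches its limits and Monte-Carlo frequency", {
  expect_identical(beneficial_probability(0, 0.4), 0)
  expect_identical(beneficial_probability(-2, 0), 0)
  expect_lt(abs(beneficial_probability(-2, 1e-6) - 0.5), 1e-9)
  p <- beneficial_probability(-2, 0.4)
  z <- sample_phenotypes(-2, 0.4, 1e5, seed = 21)
  phat <- mean(fitness_effect(z, -2) > 0)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("dfe_summary assembles row-wise summaries with the documented invariants", {
  out <- dfe_summary(data.frame(z0 = c(-2, -2, 0, -1), sigma = c(0.4, 0.05, 0.4, 1)))
  expect_s3_class(out, "dfe_summary")
  expect_equal(nrow(out), 4)
  expect_true(all(out$expected_effect <= 0))
  expect_true(all(out$max_effect == out$z0^2))
  expect_true(is.na(out$conditional_expected_effect[out$z0 == 0]))
  expect_true(all(out$conditional_expected_effect > 0, na.rm = TRUE))
  expect_error(dfe_summary(data.frame(x = 1)), "z0")
})

test_that("no perturbation beyond twice |z0| is beneficial; the scanned bound is 2", {
  b <- beneficial_magnitude_bound(-2, step = 1e-4)
  expect_lt(b$sup_beneficial, 2 * 2)
  expect_equal(b$multiple_of_z0, 2, tolerance = 1e-4)
  # directly: magnitudes above 2|z0| are deleterious for either sign
  m <- seq(4 + 1e-6, 12, length.out = 1e5)
  expect_true(all(fitness_effect(-2 + m, -2) < 0))
  expect_true(all(fitness_effect(-2 - m, -2) < 0))
})

test_that("curve and density tables carry the plotting contract", {
  cur <- dfe_curves(z0 = c(-2, -1), sigma_grid = c(0.05, 0.4, 1))
  expect_s3_class(cur, "dfe_curves")
  expect_equal(nrow(cur), 6)
  expect_s3_class(autoplot(cur), "ggplot")
  den <- dfe_density_table(z0 = -2, sigma = c(0.4, 0.05), n_grid = 64)
  expect_setequal(unique(den$variable), c("phenotype", "fitness_effect"))
  expect_true(all(den$density >= 0))
  expect_s3_class(plot_dfe_density(den), "ggplot")
})
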