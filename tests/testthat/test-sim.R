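test_that("configuration validation reports every offending field", {
  err <- tryCatch(sim_config(pop_size = 1, kappa = 2, recomb_prob = -1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "pop_size")
  expect_match(err, "kappa")
  expect_match(err, "recomb_prob")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("config files round-trip and unknown keys are named in the error", {
  cfg <- read_sim_config(system.file("extdata", "neutral_demo.yaml",
                                     package = "noisemod"))
  expect_identical(cfg$pop_size, 50L)
  expect_identical(cfg$sigma_low, cfg$sigma_high)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("pop_size: 10\nbogus_key: 1", tmp)
  expect_error(read_sim_config(tmp), "bogus_key")
})

test_that("initialization places invaders, respects monomorphism and the seed", {
  cfg <- sim_config(pop_size = 100, init_freq_high = 1 / 100)
  pop <- initialize_population(cfg, seed = 1)
  expect_equal(sum(pop$modifier == "high"), 1)
  expect_equal(nrow(pop), 100)
  cfg0 <- sim_config(pop_size = 50, init_freq_high = 0)
  expect_true(all(initialize_population(cfg0, seed = 1)$modifier == "low"))
  expect_identical(initialize_population(cfg, seed = 9),
                   initialize_population(cfg, seed = 9))
})

test_that("a generation conserves N, allele counts and the transmission rule", {
  cfg <- sim_config(pop_size = 80, sigma_low = 0.2, sigma_high = 0.4,
                    kappa = 1, recomb_prob = 0, init_freq_high = 0.5)
  pop <- initialize_population(cfg, seed = 2)
  nxt <- wf_step(pop, cfg, generation = 0, seed = 3)
  expect_equal(nrow(nxt), 80)
  expect_equal(sum(table(nxt$modifier)), 80)
  # kappa = 1: the offspring's heritable value is the parent's full phenotype
  expect_equal(nxt$g, nxt$parent_z)
  # kappa = 0: the offspring's heritable value is the parent's g
  cfg0 <- sim_config(pop_size = 80, sigma_low = 0.2, sigma_high = 0.4,
                     kappa = 0, init_freq_high = 0.5)
  nxt0 <- wf_step(pop, cfg0, generation = 0, seed = 3)
  expect_equal(nxt0$g, pop$g[nxt0$parent])
  # no recombination requested: modifiers come from the parent
  expect_false(any(nxt$recombined))
  expect_equal(as.character(nxt$modifier), as.character(pop$modifier[nxt$parent]))
})

test_that("a neutral modifier fixes at the martingale rate 1/N", {
  cfg <- sim_config(pop_size = 20, sigma_low = 0.4, sigma_high = 0.4,
                    init_freq_high = 1 / 20)
  fp <- fixation_probability(cfg, replicates = 2000, seed = 31)
  se0 <- sqrt((1 / 20) * (19 / 20) / 2000)
  expect_lt(abs(fp$fixation_prob_high - 1 / 20), 3 * se0)
  expect_identical(fp$timeouts, 0L)
})

test_that("drift dominates tiny populations and runs terminate fast", {
  cfg <- sim_config(pop_size = 2, sigma_low = 0.1, sigma_high = 0.4,
                    init_freq_high = 0.5, max_generations = 500)
  runs <- lapply(1:20, function(s) run_to_fixation(cfg, seed = s))
  expect_true(all(vapply(runs, function(r) r$outcome != "timeout", logical(1))))
  expect_lt(max(vapply(runs, function(r) r$generations, numeric(1))), 100)
})

test_that("low-noise alleles are favored at a static optimum (reduction principle)", {
  quiet <- sim_config(pop_size = 100, sigma_low = 0.4, sigma_high = 0,
                      init_freq_high = 1 / 100)
  noisy <- sim_config(pop_size = 100, sigma_low = 0, sigma_high = 0.4,
                      init_freq_high = 1 / 100)
  p_quiet <- fixation_probability(quiet, 600, seed = 41)$fixation_prob_high
  p_noisy <- fixation_probability(noisy, 600, seed = 42)$fixation_prob_high
  se0 <- sqrt(0.01 * 0.99 / 600)
  expect_gt(p_quiet - 0.01, 3 * se0)
  expect_lt(p_noisy, 0.01)
})

test_that("parent-offspring phenotype correlation rises with kappa", {
  cors <- vapply(c(0, 0.5, 1), function(k) {
    cfg <- sim_config(pop_size = 300, sigma_low = 0.4, sigma_high = 0.4,
                      kappa = k, init_freq_high = 0.5)
    h <- simulate_generations(cfg, n_generations = 15, seed = 51)
    pairs <- dplyr::bind_rows(h[-1])
    cor(pairs$parent_z, pairs$z)
  }, numeric(1))
  expect_lt(abs(cors[1]), 0.1)
  expect_true(all(diff(cors) > 0))
})

test_that("modifier-background association times scale as 1/recomb_prob", {
  mean_assoc <- function(rp) {
    cfg <- sim_config(pop_size = 400, sigma_low = 0.3, sigma_high = 0.3,
                      recomb_prob = rp, init_freq_high = 0.5)
    h <- simulate_generations(cfg, n_generations = 80, seed = 61)
    at <- association_times(h)
    mean(at$time[!at$censored])
  }
  m5 <- mean_assoc(0.2)   # expectation 5
  m10 <- mean_assoc(0.1)  # expectation 10
  expect_gt(m5 / 5, 0.7); expect_lt(m5 / 5, 1.4)
  expect_gt(m10 / 10, 0.7); expect_lt(m10 / 10, 1.4)
  expect_gt(m10, m5)
})

test_that("the adaptive lag behind a moving optimum grows with its speed", {
  lag_at <- function(v) {
    cfg <- sim_config(pop_size = 200, sigma_low = 0.4, sigma_high = 0.4,
                      kappa = 1, optimum_speed = v, init_freq_high = 0.5)
    h <- simulate_generations(cfg, n_generations = 150, seed = 71)
    lags <- vapply(seq_along(h), function(t) v * (t - 1) - mean(h[[t]]$g), numeric(1))
    mean(lags[51:length(lags)])  # discard the transient
  }
  l_slow <- lag_at(0.01)
  l_fast <- lag_at(0.05)
  expect_gt(l_fast, l_slow)
  expect_gt(l_fast, 0)
})

test_that("run objects tidy and glance; scans reproduce under a master seed", {
  cfg <- sim_config(pop_size = 30, sigma_low = 0.4, sigma_high = 0.4)
  run <- run_to_fixation(cfg, seed = 81)
  expect_s3_class(tidy(run), "tbl_df")
  expect_identical(glance(run)$outcome, run$outcome)
  expect_s3_class(autoplot(run), "ggplot")

  scan1 <- optimal_sigma_scan(cfg, sigma_grid = c(0, 0.2, 0.4),
                              replicates = 150, seed = 91)
  scan2 <- optimal_sigma_scan(cfg, sigma_grid = c(0, 0.2, 0.4),
                              replicates = 150, seed = 91)
  expect_identical(as.data.frame(scan1), as.data.frame(scan2))
  expect_s3_class(autoplot(scan1), "ggplot")
  expect_equal(nrow(glance(scan1)), 1)
})

test_that("at a static optimum the optimal noise magnitude is the smallest scanned", {
  cfg <- sim_config(pop_size = 100, sigma_low = 0, sigma_high = 0.4,
                    init_freq_high = 1 / 100)
  scan <- optimal_sigma_scan(cfg, sigma_grid = c(0, 0.2, 0.4),
                             replicates = 600, seed = 95)
  expect_identical(scan$sigma[scan$is_argmax], 0)
})

test_that("the N-scan classifies noise as disfavored at a static optimum and validates input", {
  cfg <- sim_config(pop_size = 100, sigma_low = 0, sigma_high = 0.4)
  expect_error(sign_inversion_scan(cfg, c(20, 50, 200), replicates = 0), "replicates")
  expect_error(sign_inversion_scan(cfg, c(50, 20, 200), replicates = 100), "ascending")
  expect_error(sign_inversion_scan(cfg, c(20, 50), replicates = 100), "at least 3")
  scan <- sign_inversion_scan(cfg, c(20, 50, 200), replicates = 2500, seed = 99)
  expect_identical(scan$direction[scan$pop_size >= 50],
                   rep("disfavored", 2))
  expect_lte(attr(scan, "direction_changes"), 1)
})
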