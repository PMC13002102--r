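# Internal engine state is a plain list of parallel vectors: `modifier`
# (integer, 0 = low, 1 = high), `g` (heritable value), `z` (realized
# phenotype). Tibbles appear only at the public surface; the hot loop stays
# base-vector.

allele_levels <- c("low", "high")

pop_to_tibble <- function(state, extra = NULL) {
  out <- tibble(
    modifier = factor(allele_levels[state$modifier + 1L], levels = allele_levels),
    g = state$g,
    z = state$z
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  class(out) <- c("wf_population", class(out))
  out
}

tibble_to_pop <- function(pop) {
  stopifnot(is.data.frame(pop), all(c("modifier", "g", "z") %in% names(pop)))
  mod <- if (is.factor(pop$modifier) || is.character(pop$modifier)) {
    as.integer(as.character(pop$modifier) == "high")
  } else {
    as.integer(pop$modifier)
  }
  list(modifier = mod, g = as.numeric(pop$g), z = as.numeric(pop$z))
}

init_state <- function(cfg, n_high = NULL) {
  N <- cfg$pop_size
  n_high <- n_high %||% as.integer(round(cfg$init_freq_high * N))
  mod <- c(rep(1L, n_high), rep(0L, N - n_high))
  g <- rep(-cfg$init_offset, N)
  sig <- ifelse(mod == 1L, cfg$sigma_high, cfg$sigma_low)
  list(modifier = mod, g = g, z = g + rnorm(N, 0, sig))
}

# One Wright-Fisher generation. Selection weights are exp(r) (Malthusian
# fitness mapped to discrete-generation viability); the common factor
# exp(r_optimum - max r) is divided out for numerical stability and does
# not change the multinomial draw.
wf_generation <- function(state, cfg, t) {
  N <- length(state$modifier)
  r <- -(cfg$optimum_speed * t - state$z)^2
  w <- exp(r - max(r))
  parent <- sample.int(N, N, replace = TRUE, prob = w)
  off_mod <- state$modifier[parent]
  rec <- rep(FALSE, N)
  if (cfg$recomb_prob > 0) {
    rec <- runif(N) < cfg$recomb_prob
    if (any(rec)) {
      donor <- sample.int(N, sum(rec), replace = TRUE, prob = w)
      off_mod[rec] <- state$modifier[donor]
    }
  }
  off_g <- state$g[parent] + cfg$kappa * (state$z[parent] - state$g[parent])
  sig <- ifelse(off_mod == 1L, cfg$sigma_high, cfg$sigma_low)
  list(modifier = off_mod, g = off_g, z = off_g + rnorm(N, 0, sig),
       parent = parent, recombined = rec)
}

#' Initialize a noise-modifier population
#'
#' Creates the generation-0 population for a [sim_config()]: `round(
#' init_freq_high * N)` carriers of the `high` allele, heritable values at
#' the optimum's starting position minus `init_offset`, and phenotypes
#' drawn with each carrier's own noise magnitude.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A tibble of class `"wf_population"` with one row per individual:
#'   `modifier` (factor `low`/`high`), `g`, `z`.
#' @examples
#' initialize_population(sim_config(pop_size = 10, init_freq_high = 0.1), seed = 1)
#' @export
initialize_population <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  run <- function() pop_to_tibble(init_state(config))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Advance a population one Wright-Fisher generation
#'
#' Applies one cycle of selection, reproduction, transmission, and fresh
#' noise: the optimum sits at `optimum_speed * generation`; each individual's
#' selection weight is `exp(r)` with `r` the quadratic Malthusian fitness of
#' its realized phenotype; `N` offspring choose parents multinomially;
#' each offspring inherits `g + kappa * (z - g)` from its parent, keeps the
#' parental modifier allele except with probability `recomb_prob` (then it
#' copies the allele of a second, independently fitness-weighted parent),
#' and realizes a fresh perturbation with its own allele's noise magnitude.
#'
#' @param population A `"wf_population"` tibble (see
#'   [initialize_population()]).
#' @inheritParams initialize_population
#' @param generation Generation index `t` (sets the optimum position).
#' @return A `"wf_population"` tibble with bookkeeping columns `parent`
#'   (row index of the parent), `parent_z` (parent's realized phenotype),
#'   and `recombined` (whether the modifier came from a second parent).
#' @examples
#' cfg <- sim_config(pop_size = 20, sigma_low = 0.1, sigma_high = 0.4)
#' pop <- initialize_population(cfg, seed = 1)
#' wf_step(pop, cfg, generation = 0, seed = 2)
#' @export
wf_step <- function(population, config, generation = 0, seed = NULL) {
  config <- validate_sim_config(config)
  state <- tibble_to_pop(population)
  if (length(state$modifier) < 1) abort("`population` must be non-empty.")
  run <- function() {
    nxt <- wf_generation(state, config, generation)
    pop_to_tibble(nxt, extra = tibble(parent = nxt$parent,
                                      parent_z = state$z[nxt$parent],
                                      recombined = nxt$recombined))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run one replicate until a modifier allele fixes
#'
#' Iterates [wf_step()]'s dynamics until the `high` allele is fixed or lost,
#' or `max_generations` post-invasion generations elapse (a timeout). With
#' `burn_in > 0`, the population first evolves monomorphic for the `low`
#' allele, after which the invaders replace randomly chosen residents.
#'
#' @inheritParams initialize_population
#' @param keep_trajectory Record the per-generation allele frequency and
#'   mean heritable value (costs memory; scans switch it off).
#' @return A list of class `"wf_run"`: `outcome` (`"high"`, `"low"` or
#'   `"timeout"`), `fixed_allele` (`NA` on timeout), `generations`
#'   (post-invasion), `mean_lag` (time-averaged `z_opt(t) - mean(g)`),
#'   `final_freq_high`, `trajectory` (tibble or `NULL`), `config`, `seed`.
#'   [tidy()] returns the trajectory, [glance()] the one-row summary.
#' @examples
#' cfg <- sim_config(pop_size = 30, sigma_low = 0.4, sigma_high = 0.4)
#' glance(run_to_fixation(cfg, seed = 1))
#' @export
run_to_fixation <- function(config, seed = NULL, keep_trajectory = TRUE) {
  config <- validate_sim_config(config)
  if (config$init_freq_high <= 0 || config$init_freq_high >= 1) {
    abort("run_to_fixation() needs 0 < init_freq_high < 1 (both alleles segregating).")
  }
  n_high0 <- as.integer(round(config$init_freq_high * config$pop_size))
  if (n_high0 < 1 || n_high0 >= config$pop_size) {
    abort("init_freq_high rounds to a monomorphic population at this pop_size.")
  }
  run <- function() {
    N <- config$pop_size
    t <- 0L
    if (config$burn_in > 0) {
      state <- init_state(config, n_high = 0L)
      for (i in seq_len(config$burn_in)) {
        state <- wf_generation(state, config, t)
        t <- t + 1L
      }
      state$modifier[sample.int(N, n_high0)] <- 1L
      # invaders' phenotypes were realized under the resident sigma; their
      # offspring feel the new allele from the next generation on
    } else {
      state <- init_state(config)
    }
    gens <- 0L
    lag_sum <- 0
    traj_f <- traj_g <- if (keep_trajectory) numeric(config$max_generations + 1L) else NULL
    repeat {
      k <- sum(state$modifier)
      lag <- config$optimum_speed * t - mean(state$g)
      lag_sum <- lag_sum + lag
      if (keep_trajectory) {
        traj_f[gens + 1L] <- k / N
        traj_g[gens + 1L] <- mean(state$g)
      }
      if (k == 0L || k == N || gens >= config$max_generations) break
      state <- wf_generation(state, config, t)
      t <- t + 1L
      gens <- gens + 1L
    }
    k <- sum(state$modifier)
    outcome <- if (k == N) "high" else if (k == 0L) "low" else "timeout"
    trajectory <- NULL
    if (keep_trajectory) {
      gen_idx <- 0:gens
      trajectory <- tibble(
        generation = gen_idx,
        freq_high = traj_f[gen_idx + 1L],
        mean_g = traj_g[gen_idx + 1L],
        optimum = config$optimum_speed * (t - gens + gen_idx),
        lag = .data$optimum - .data$mean_g
      )
    }
    structure(list(
      outcome = outcome,
      fixed_allele = if (outcome == "timeout") NA_character_ else outcome,
      generations = gens,
      mean_lag = lag_sum / (gens + 1L),
      final_freq_high = k / N,
      trajectory = trajectory,
      config = config,
      seed = seed
    ), class = "wf_run")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.wf_run <- function(x, ...) {
  cat(sprintf("Wright-Fisher run: %s after %d generations (final high-allele frequency %.3f)\n",
              switch(x$outcome, high = "high allele fixed",
                     low = "high allele lost", timeout = "timeout"),
              x$generations, x$final_freq_high))
  cat(sprintf("  time-averaged lag behind the optimum: %.4f\n", x$mean_lag))
  invisible(x)
}

replicate_seeds <- function(seed, n) {
  if (is.null(seed)) {
    sample.int(.Machine$integer.max, n)
  } else {
    withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  }
}

#' Estimate the fixation probability of the high-noise allele
#'
#' Runs independent replicates of [run_to_fixation()] and reports the
#' fraction in which the `high` allele fixed, with its binomial standard
#' error. Replicate seeds are derived deterministically from the master
#' seed, so results are reproducible and replicates are independent.
#' Timeouts count as non-fixation and are reported.
#'
#' @inheritParams initialize_population
#' @param replicates Number of replicates (at least 1; hundreds or more for
#'   a useful standard error).
#' @return One-row tibble: the configuration's key parameters, then
#'   `fixation_prob_high`, `se` (binomial SE of the estimate),
#'   `neutral_expectation` (`init_freq_high`, the martingale prediction for
#'   a neutral modifier), `mean_lag` (averaged over replicates),
#'   `replicates`, `timeouts`.
#' @examples
#' cfg <- sim_config(pop_size = 20, sigma_low = 0.4, sigma_high = 0.4)
#' fixation_probability(cfg, replicates = 200, seed = 1)
#' @export
fixation_probability <- function(config, replicates, seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1) {
    abort("`replicates` must be a positive count.")
  }
  replicates <- as.integer(replicates)
  seeds <- replicate_seeds(seed, replicates)
  fixed_high <- logical(replicates)
  lag <- numeric(replicates)
  timeout <- logical(replicates)
  for (i in seq_len(replicates)) {
    run <- run_to_fixation(config, seed = seeds[i], keep_trajectory = FALSE)
    fixed_high[i] <- identical(run$outcome, "high")
    timeout[i] <- identical(run$outcome, "timeout")
    lag[i] <- run$mean_lag
  }
  p <- mean(fixed_high)
  tibble(
    pop_size = config$pop_size,
    sigma_low = config$sigma_low, sigma_high = config$sigma_high,
    kappa = config$kappa, recomb_prob = config$recomb_prob,
    optimum_speed = config$optimum_speed,
    fixation_prob_high = p,
    se = sqrt(p * (1 - p) / replicates),
    neutral_expectation = config$init_freq_high,
    mean_lag = mean(lag),
    replicates = replicates,
    timeouts = sum(timeout)
  )
}

classify_direction <- function(p_hat, p_neutral, replicates) {
  se0 <- sqrt(p_neutral * (1 - p_neutral) / replicates)
  dplyr::case_when(
    p_hat - p_neutral > 3 * se0 ~ "favored",
    p_neutral - p_hat > 3 * se0 ~ "disfavored",
    TRUE ~ "neutral-indistinguishable"
  )
}

#' Scan the direction of selection on the high-noise allele across N
#'
#' For each population size on the grid, estimates the fixation probability
#' of a single high-allele invader and classifies the direction of selection
#' against the neutral expectation `1/N` at the 3-standard-error level
#' (standard error taken under the neutral null). Small populations are
#' expected to be neutral-indistinguishable (the drift barrier); where the
#' direction changes along the grid is reported, not asserted.
#'
#' @param config_template A [sim_config()]; `pop_size` and `init_freq_high`
#'   are overridden per grid point (single invader), all else is shared.
#' @param N_grid Ascending population sizes, at least 3.
#' @inheritParams fixation_probability
#' @return A tibble of class `"noise_scan"`, one row per `N`: the
#'   [fixation_probability()] columns plus `direction`; attribute
#'   `direction_changes` counts sign changes among non-neutral
#'   classifications.
#' @export
sign_inversion_scan <- function(config_template, N_grid, replicates, seed = NULL) {
  config_template <- validate_sim_config(config_template)
  if (!is.numeric(N_grid) || length(N_grid) < 3 || is.unsorted(N_grid, strictly = TRUE)) {
    abort("`N_grid` must be an ascending vector of at least 3 population sizes.")
  }
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1) {
    abort("`replicates` must be a positive count.")
  }
  seeds <- replicate_seeds(seed, length(N_grid))
  rows <- purrr::map2_dfr(N_grid, seeds, function(N, s) {
    cfg <- config_template
    cfg$pop_size <- as.integer(N)
    cfg$init_freq_high <- 1 / N
    cfg$max_generations <- max(config_template$max_generations, 50L * as.integer(N))
    cfg <- validate_sim_config(cfg)
    fixation_probability(cfg, replicates, seed = s)
  })
  rows$direction <- classify_direction(rows$fixation_prob_high,
                                       1 / rows$pop_size, rows$replicates)
  signs <- c(favored = 1, disfavored = -1)[rows$direction]
  signs <- signs[!is.na(signs)]
  attr(rows, "direction_changes") <- if (length(signs) > 1) sum(diff(signs) != 0) else 0L
  attr(rows, "scan_type") <- "pop_size"
  class(rows) <- c("noise_scan", class(rows))
  rows
}

#' Scan invasion success across noise magnitudes
#'
#' For each `sigma` on the grid, estimates the fixation probability of an
#' invading allele with that noise magnitude against a fixed resident
#' (`sigma_ref`), and marks the grid argmax together with the band of grid
#' points statistically indistinguishable from it (3 combined standard
#' errors). The argmax locates the selectively optimal amount of noise on
#' the grid under the configured regime.
#'
#' @inheritParams sign_inversion_scan
#' @param sigma_grid Noise magnitudes to scan, at least 3.
#' @param sigma_ref Resident noise magnitude; defaults to the template's
#'   `sigma_low`.
#' @return A tibble of class `"noise_scan"`, one row per `sigma`, with
#'   `is_argmax` and `in_argmax_band` columns.
#' @export
optimal_sigma_scan <- function(config_template, sigma_grid, replicates,
                               seed = NULL, sigma_ref = config_template$sigma_low) {
  config_template <- validate_sim_config(config_template)
  if (!is.numeric(sigma_grid) || length(sigma_grid) < 3 || any(sigma_grid < 0)) {
    abort("`sigma_grid` must be at least 3 non-negative noise magnitudes.")
  }
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1) {
    abort("`replicates` must be a positive count.")
  }
  seeds <- replicate_seeds(seed, length(sigma_grid))
  rows <- purrr::map2_dfr(sigma_grid, seeds, function(sig, s) {
    cfg <- config_template
    cfg$sigma_high <- sig
    cfg$sigma_low <- sigma_ref
    cfg <- validate_sim_config(cfg)
    res <- fixation_probability(cfg, replicates, seed = s)
    dplyr::mutate(res, sigma = sig, .before = 1)
  })
  imax <- which.max(rows$fixation_prob_high)
  rows$is_argmax <- seq_len(nrow(rows)) == imax
  band_se <- sqrt(rows$se^2 + rows$se[imax]^2)
  rows$in_argmax_band <- (rows$fixation_prob_high[imax] - rows$fixation_prob_high) <=
    3 * band_se
  attr(rows, "scan_type") <- "sigma"
  class(rows) <- c("noise_scan", class(rows))
  rows
}

#' Simulate and keep a per-generation history
#'
#' Runs a fixed number of generations recording every intermediate
#' population with its parentage bookkeeping — the raw material for
#' measuring the parent-offspring phenotype correlation induced by `kappa`
#' and the modifier-background association times induced by `recomb_prob`.
#'
#' @inheritParams initialize_population
#' @param n_generations Number of generations to record (beyond generation 0).
#' @return List of `"wf_population"` tibbles of length `n_generations + 1`;
#'   from generation 1 on, each has `parent`, `parent_z`, `recombined`.
#' @examples
#' cfg <- sim_config(pop_size = 30, sigma_low = 0.3, sigma_high = 0.3, kappa = 1)
#' h <- simulate_generations(cfg, n_generations = 5, seed = 1)
#' @export
simulate_generations <- function(config, n_generations, seed = NULL) {
  config <- validate_sim_config(config)
  stopifnot(n_generations >= 1)
  run <- function() {
    state <- init_state(config)
    history <- vector("list", n_generations + 1L)
    history[[1]] <- pop_to_tibble(state)
    for (t in seq_len(n_generations)) {
      nxt <- wf_generation(state, config, t - 1L)
      history[[t + 1L]] <- pop_to_tibble(
        nxt, extra = tibble(parent = nxt$parent, parent_z = state$z[nxt$parent],
                            recombined = nxt$recombined)
      )
      state <- nxt
    }
    history
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generations since a modifier allele joined its heritable background
#'
#' Walks each final-generation individual's pedigree backwards through a
#' [simulate_generations()] history until the most recent decoupling event
#' (an offspring whose modifier came from a second parent), and reports the
#' number of generations elapsed. Under per-offspring decoupling probability
#' `recomb_prob` these times are geometric with mean `1/recomb_prob`;
#' lineages with no event in the recorded window are censored at the window
#' length.
#'
#' @param history A list of generations from [simulate_generations()].
#' @return Tibble with one row per final-generation individual: `time`
#'   (generations since decoupling) and `censored`.
#' @export
association_times <- function(history) {
  stopifnot(is.list(history), length(history) >= 2)
  n_gen <- length(history) - 1L
  n <- nrow(history[[length(history)]])
  time <- integer(n)
  censored <- logical(n)
  for (i in seq_len(n)) {
    idx <- i
    t <- 0L
    gen <- length(history)
    repeat {
      if (gen < 2L) { censored[i] <- TRUE; break }
      row <- history[[gen]][idx, ]
      t <- t + 1L
      if (isTRUE(row$recombined)) break
      idx <- row$parent
      gen <- gen - 1L
    }
    time[i] <- min(t, n_gen)
  }
  tibble(time = time, censored = censored)
}
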