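#' Configure a noise-modifier Wright-Fisher simulation
#'
#' Builds and validates the parameter set for the individual-based simulator
#' of two competing noise-modifier alleles (`low` and `high`). Each
#' individual carries a modifier allele, a heritable trait value `g`, and a
#' realized phenotype `z = g + noise`, where the noise is drawn fresh each
#' generation with the standard deviation set by the individual's allele.
#' The modifier acts only through this noise magnitude — it never shifts
#' the expected phenotype, so all selection on it is indirect.
#'
#' Two knobs span the spectrum of association between a modifier allele and
#' the phenotypic perturbations it induces:
#' \describe{
#'   \item{`kappa`}{fraction of a parent's realized perturbation
#'     (`z - g`) written into the offspring's heritable value. `kappa = 1`
#'     with `recomb_prob = 0` is the asexual-mutator limit (perturbations
#'     are permanently inherited alongside the allele that caused them);
#'     `kappa = 0` is the uncorrelated limit in which parent and offspring
#'     phenotypes share only `g`.}
#'   \item{`recomb_prob`}{per-offspring probability that the modifier allele
#'     is copied from an independently chosen second parent instead of the
#'     parent that supplied everything else — an abstraction of
#'     recombination decoupling the modifier from the background it shaped.
#'     The expected association time is `1 / recomb_prob` generations.}
#' }
#'
#' @param pop_size Census population size `N` (constant; at least 2).
#' @param sigma_low,sigma_high Noise magnitudes of the two alleles.
#' @param kappa Transmitted fraction of the parental perturbation, in `[0, 1]`.
#' @param recomb_prob Per-offspring modifier decoupling probability, in `[0, 1]`.
#' @param optimum_speed Speed `v` of the moving phenotypic optimum,
#'   `z_opt(t) = v t` (trait units per generation).
#' @param r_optimum Malthusian fitness at the optimum; shifts all selection
#'   weights by a common factor and is irrelevant to the dynamics.
#' @param init_freq_high Initial frequency of the `high` allele; `1/N` plants
#'   a single invader.
#' @param init_offset Initial displacement of every heritable value below the
#'   optimum: `g(0) = z_opt(0) - init_offset`. A positive offset starts the
#'   population maladapted (its expected phenotype plays the role of an
#'   off-optimum `z0`).
#' @param burn_in Generations run with a monomorphic `low` population before
#'   the `high` allele is introduced.
#' @param max_generations Cap on generations after which a run is declared a
#'   timeout. Default `50 * pop_size`, generous for neutral absorption.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' sim_config(pop_size = 100, sigma_low = 0, sigma_high = 0.4)
#' @export
sim_config <- function(pop_size = 100,
                       sigma_low = 0,
                       sigma_high = 0.4,
                       kappa = 0,
                       recomb_prob = 0,
                       optimum_speed = 0,
                       r_optimum = 0,
                       init_freq_high = 1 / pop_size,
                       init_offset = 0,
                       burn_in = 0,
                       max_generations = 50 * pop_size) {
  cfg <- list(pop_size = as.integer(pop_size), sigma_low = sigma_low,
              sigma_high = sigma_high, kappa = kappa,
              recomb_prob = recomb_prob, optimum_speed = optimum_speed,
              r_optimum = r_optimum, init_freq_high = init_freq_high,
              init_offset = init_offset, burn_in = as.integer(burn_in),
              max_generations = as.integer(max_generations))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  chk(num1(cfg$pop_size) && cfg$pop_size >= 2, "pop_size: must be an integer >= 2")
  chk(num1(cfg$sigma_low) && cfg$sigma_low >= 0, "sigma_low: must be >= 0")
  chk(num1(cfg$sigma_high) && cfg$sigma_high >= 0, "sigma_high: must be >= 0")
  chk(num1(cfg$kappa) && cfg$kappa >= 0 && cfg$kappa <= 1, "kappa: must be in [0, 1]")
  chk(num1(cfg$recomb_prob) && cfg$recomb_prob >= 0 && cfg$recomb_prob <= 1,
      "recomb_prob: must be in [0, 1]")
  chk(num1(cfg$optimum_speed), "optimum_speed: must be a number")
  chk(num1(cfg$r_optimum), "r_optimum: must be a number")
  chk(num1(cfg$init_freq_high) && cfg$init_freq_high >= 0 && cfg$init_freq_high <= 1,
      "init_freq_high: must be in [0, 1]")
  chk(num1(cfg$init_offset), "init_offset: must be a number")
  chk(num1(cfg$burn_in) && cfg$burn_in >= 0, "burn_in: must be >= 0")
  chk(num1(cfg$max_generations) && cfg$max_generations >= 1,
      "max_generations: must be >= 1")
  if (length(problems)) {
    abort(c("invalid simulation configuration:", problems))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Noise-modifier Wright-Fisher configuration\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are an error
#' (listed by name), missing keys take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(c("unknown configuration keys:", bad,
            paste0("valid keys: ", paste(known, collapse = ", "))))
  }
  do.call(sim_config, raw)
}
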