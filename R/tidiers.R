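#' Tidy a Wright-Fisher run
#'
#' @param x A `"wf_run"` from [run_to_fixation()].
#' @param ... Unused.
#' @return The per-generation trajectory as a tibble (`generation`,
#'   `freq_high`, `mean_g`, `optimum`, `lag`). Errors if the run was made
#'   with `keep_trajectory = FALSE`.
#' @export
tidy.wf_run <- function(x, ...) {
  if (is.null(x$trajectory)) {
    abort("this run was made with `keep_trajectory = FALSE`; no trajectory to tidy.")
  }
  x$trajectory
}

#' Summarize a Wright-Fisher run in one row
#'
#' @inheritParams tidy.wf_run
#' @return One-row tibble: `outcome`, `fixed_allele`, `generations`,
#'   `mean_lag`, `final_freq_high`.
#' @export
glance.wf_run <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    fixed_allele = x$fixed_allele,
    generations = x$generations,
    mean_lag = x$mean_lag,
    final_freq_high = x$final_freq_high
  )
}

#' Summarize a parameter scan in one row
#'
#' @param x A `"noise_scan"` from [optimal_sigma_scan()] or
#'   [sign_inversion_scan()].
#' @param ... Unused.
#' @return For a sigma scan: the argmax noise magnitude, its fixation
#'   probability and standard error, and the width of the argmax band. For
#'   a population-size scan: the per-direction counts and the number of
#'   direction changes along the grid.
#' @export
glance.noise_scan <- function(x, ...) {
  if (identical(attr(x, "scan_type"), "sigma")) {
    best <- x[x$is_argmax, ]
    tibble(
      sigma_optimal = best$sigma,
      fixation_prob_high = best$fixation_prob_high,
      se = best$se,
      band_size = sum(x$in_argmax_band)
    )
  } else {
    tibble(
      n_favored = sum(x$direction == "favored"),
      n_disfavored = sum(x$direction == "disfavored"),
      n_neutral = sum(x$direction == "neutral-indistinguishable"),
      direction_changes = attr(x, "direction_changes") %||% NA_integer_
    )
  }
}
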