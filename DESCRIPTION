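Package: noisemod
Title: Population Genetics of Biological Noise Modifier Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying natural selection on alleles that modify the
    amount of biological noise in their carriers. Implements a stochastic model
    in which Gaussian phenotypic perturbations pass through a quadratic
    Malthusian fitness map, yielding a closed-form distribution of fitness
    effects with an exactly computable unconditioned mean and a
    beneficial-conditioned mean; independent Monte-Carlo and quadrature
    oracles for every closed form; and an individual-based Wright-Fisher
    simulator of competing noise-modifier alleles under a moving phenotypic
    optimum, with tunable parent-offspring phenotype association and
    modifier-background decoupling. Includes a command-line interface for
    exporting model curves and running fixation-probability scans over
    noise magnitude and population size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
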