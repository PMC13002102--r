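# Standard parameter grid used by the density/expectation property tests.
standard_grid <- function() {
  tidyr::expand_grid(z0 = c(-2, -1, -0.1), sigma = c(0.05, 0.4, 1, 4))
}
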