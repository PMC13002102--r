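# Neutral demonstration: both modifier alleles carry the same noise
# magnitude, so the high allele's fixation probability must match the
# martingale expectation init_freq_high = 1/N.
pop_size: 50
sigma_low: 0.4
sigma_high: 0.4
kappa: 0
recomb_prob: 0
optimum_speed: 0
init_freq_high: 0.02
init_offset: 0
max_generations: 2500
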