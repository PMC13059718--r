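## shared helpers for the test suite

## canonical parameter set (the package defaults)
canonical <- function(...) model_params(...)

## noiseless variant of a scenario noise specification
no_noise <- function() list(confluence = 0, ratio = 0, dead_count_scale = 500)

## relative error helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)

## a small noiseless single-condition dataset used by several fitting tests
make_clean_synthetic <- function(name = "MD_RSL3", seeding = "MD", n0 = 0.22,
                                 r0_multiplier = 0.4, duration_h = 72,
                                 replicates = 1, seed = 1L) {
  generate_dataset(scenario(name, seeding, n0 = n0,
                            r0_multiplier = r0_multiplier,
                            duration_h = duration_h, replicates = replicates,
                            noise = no_noise(), seed = seed))
}
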