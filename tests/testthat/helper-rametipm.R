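# shared fixtures, built in code
ref <- reference_params()

# parameter set with survival forced to 1 (degenerate Bernoulli surrogate
# for beta0_s -> +Inf)
immortal_params <- function(p = reference_params()) {
  p$beta0_s <- 40
  p$beta1_s <- 0
  p
}

# a small, reproducible study-sized dataset
study_data <- function(seed = 1, n = 276) {
  simulate_ramets(reference_params(), n, seed = seed)
}

expect_within <- function(est, truth, halfwidth) {
  expect_lt(abs(est - truth), halfwidth)
}
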