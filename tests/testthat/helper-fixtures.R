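# Shared fixtures built in code.

# A registry whose sigma does not depend on mu (handy for monotonicity and
# symmetry checks where the flow dependence would get in the way).
constant_sigma_registry <- function(sigma = 0.1) {
  calibration_registry(
    device_calibration("flat", c(sigma, 0), valid_range = c(0.5, 5),
                       provenance = "test fixture: constant sigma")
  )
}

# Noiseless test-retest records lying exactly on a polynomial sigma(mu).
noiseless_records <- function(coefficients, mus = seq(1, 4, length.out = 10)) {
  sd_true <- vo2overlap:::eval_poly(coefficients, mus)
  out <- data.frame(
    subject_id = NA_character_, workload = NA_character_,
    mean_vo2 = mus, sd_vo2 = sd_true, stringsAsFactors = FALSE
  )
  class(out) <- c("test_retest_records", "data.frame")
  out
}

# Random overlap parameter sets for property sweeps, reproducible.
random_ovl_params <- function(n, seed, equal_fraction = 0.2) {
  set.seed(seed)
  data.frame(
    mu1 = runif(n, -2, 5),
    mu2 = runif(n, -2, 5),
    sigma1 = runif(n, 0.05, 1.5),
    sigma2 = ifelse(runif(n) < equal_fraction, NA, runif(n, 0.05, 1.5))
  )
}
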