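# Synthetic two-day, multi-workload test-retest protocols with differential
# (flow-dependent) measurement error, for validating the calibration fit and
# the full pipeline without any external data.

#' Define a synthetic test-retest protocol
#'
#' Describes a two-day protocol in which each subject's VO2 is measured at a
#' grid of workloads on two different days, with day-to-day error that grows
#' with the true VO2 level: each observed measure is drawn as
#' Normal(X, sigma_true(X)) where sigma_true is a polynomial in the true
#' value X. This is the differential-error analogue of the classical
#' constant-error model W = X + U.
#'
#' The default workload grid (1.0 to 4.0 L/min in 0.5 steps) spans the range
#' of a typical incremental cycling protocol; the default noise polynomial is
#' a mildly increasing curve of realistic magnitude (about 0.04 L/min at
#' 1 L/min rising to about 0.17 L/min at 4 L/min, i.e. a 3-6% coefficient of
#' variation, in line with published day-to-day reproducibility of metabolic
#' carts).
#'
#' @param workload_mus True VO2 values X (L/min) at the protocol workloads.
#' @param n_subjects Number of subjects; each contributes one pair per
#'   workload.
#' @param noise_coefficients Ascending polynomial coefficients of
#'   sigma_true(X) (L/min); sigma_true must be positive at every workload.
#' @param seed Integer seed; required, so every dataset is reproducible.
#' @return An object of class `synthetic_protocol`.
#' @export
synthetic_protocol <- function(workload_mus = seq(1.0, 4.0, by = 0.5),
                               n_subjects = 10L,
                               noise_coefficients = c(0.02, 0.015, 0.005),
                               seed) {
  if (missing(seed)) abort_invalid_input("`seed` is required (no hidden global RNG)")
  check_scalar_number(seed, "seed")
  if (!is.numeric(workload_mus) || length(workload_mus) == 0L ||
      any(workload_mus <= 0)) {
    abort_invalid_input("`workload_mus` must be positive VO2 values (L/min)")
  }
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    abort_invalid_input("`n_subjects` must be >= 1")
  }
  sig <- eval_poly(noise_coefficients, workload_mus)
  if (any(sig < 0)) { # exactly zero is permitted as the degenerate noise-free case
    abort_invalid_input("sigma_true(X) must be non-negative at every workload")
  }
  structure(
    list(
      workload_mus = as.numeric(workload_mus),
      n_subjects = n_subjects,
      noise_coefficients = as.numeric(noise_coefficients),
      seed = as.integer(seed)
    ),
    class = "synthetic_protocol"
  )
}

#' Simulate one two-day measurement pair
#'
#' Draws the day-1 and day-2 observed values independently from
#' Normal(X, sigma_true(X)), truncated at zero by resampling (an observed
#' VO2 cannot be non-positive). Uses the current RNG state; seed control
#' belongs to the caller (see [generate_test_retest()]).
#'
#' @param X True VO2 (L/min); positive.
#' @param noise_coefficients Ascending polynomial coefficients of
#'   sigma_true(X). A zero polynomial is permitted (degenerate, noise-free).
#' @return Named numeric vector `c(day1 = , day2 = )`.
#' @export
simulate_measurement_pair <- function(X, noise_coefficients) {
  check_scalar_number(X, "X", positive = TRUE)
  sigma <- eval_poly(noise_coefficients, X)
  if (sigma < 0) {
    abort_invalid_input(sprintf("sigma_true(%g) = %g < 0", X, sigma))
  }
  if (sigma == 0) return(c(day1 = X, day2 = X))
  draw <- function() {
    repeat {
      w <- stats::rnorm(1L, X, sigma)
      if (w > 0) return(w)
    }
  }
  c(day1 = draw(), day2 = draw())
}

#' Generate a full synthetic test-retest dataset
#'
#' One [test_retest_records()] row per (subject, workload): the mean and SD
#' of that subject's simulated two-day pair. Fully reproducible from the
#' protocol's seed; the caller's RNG state is saved and restored.
#'
#' @param protocol A [synthetic_protocol()].
#' @return A `test_retest_records` data.frame with
#'   `n_subjects * length(workload_mus)` rows.
#' @export
generate_test_retest <- function(protocol) {
  if (!inherits(protocol, "synthetic_protocol")) {
    abort_invalid_input("`protocol` must be a synthetic_protocol")
  }
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(protocol$seed)

  grid <- expand.grid(
    subject = seq_len(protocol$n_subjects),
    workload_idx = seq_along(protocol$workload_mus)
  )
  pairs <- t(vapply(seq_len(nrow(grid)), function(i) {
    simulate_measurement_pair(
      protocol$workload_mus[grid$workload_idx[i]],
      protocol$noise_coefficients
    )
  }, numeric(2)))
  test_retest_records(
    day1 = pairs[, 1], day2 = pairs[, 2],
    subject_id = sprintf("S%02d", grid$subject),
    workload = sprintf("W%d", grid$workload_idx)
  )
}

#' Write test-retest records as a calibration CSV
#'
#' Emits the dialect consumed by [read_calibration_csv()] /
#' `cli calibrate`: columns `subject_id`, `workload`, `mean_vo2`, `sd_vo2`.
#'
#' @param records A `test_retest_records` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(records, path) {
  if (!is.data.frame(records) ||
      !all(c("mean_vo2", "sd_vo2") %in% names(records))) {
    abort_invalid_input("`records` must have columns mean_vo2 and sd_vo2")
  }
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
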