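# Device error model: a per-device polynomial mapping measured VO2 (L/min)
# to the standard deviation of its day-to-day error distribution.

# Hard physiologic envelope for any VO2 input, L/min. Outside the device's
# valid_range but inside this envelope we warn and extrapolate; outside it we
# refuse.
VO2_ENVELOPE <- c(0.3, 6.0)

#' Construct a device calibration
#'
#' A calibration is a polynomial \eqn{\sigma(\mu) = \sum_i c_i \mu^i} giving
#' the day-to-day standard deviation (L/min) of a device's VO2 measurement at
#' measured level \eqn{\mu} (L/min), together with the \eqn{\mu} interval on
#' which it is considered valid. Positivity of \eqn{\sigma} over the valid
#' range is checked on a dense grid at construction.
#'
#' @param device_id Device label, e.g. `"parvo_2400"` or `"douglas_bag"`.
#' @param coefficients Numeric vector of polynomial coefficients in ascending
#'   order (`c0, c1, ...`); length is polynomial order + 1, order at most 3.
#' @param valid_range Closed interval `c(mu_min, mu_max)` in L/min with
#'   `0 < mu_min < mu_max`.
#' @param provenance Free-text note on where the calibration came from.
#' @return An object of class `device_calibration`.
#' @export
device_calibration <- function(device_id, coefficients,
                               valid_range = c(1.0, 4.0),
                               provenance = "") {
  if (!is.character(device_id) || length(device_id) != 1L || !nzchar(device_id)) {
    abort_invalid_input("`device_id` must be a non-empty string")
  }
  if (!is.numeric(coefficients) || length(coefficients) < 2L ||
      length(coefficients) > 4L || any(!is.finite(coefficients))) {
    abort_invalid_input(
      "`coefficients` must be 2 to 4 finite numbers (polynomial order 1 to 3, ascending)"
    )
  }
  if (!is.numeric(valid_range) || length(valid_range) != 2L ||
      any(!is.finite(valid_range)) || valid_range[1] <= 0 ||
      valid_range[1] >= valid_range[2]) {
    abort_invalid_input("`valid_range` must be c(mu_min, mu_max) with 0 < mu_min < mu_max")
  }
  cal <- structure(
    list(
      device_id = device_id,
      coefficients = as.numeric(coefficients),
      order = length(coefficients) - 1L,
      valid_range = as.numeric(valid_range),
      provenance = as.character(provenance)
    ),
    class = "device_calibration"
  )
  grid <- seq(valid_range[1], valid_range[2], length.out = 512L)
  sig <- eval_poly(cal$coefficients, grid)
  if (any(sig <= 0)) {
    bad <- grid[which(sig <= 0)[1]]
    abort_calibration_domain(sprintf(
      "calibration '%s' gives sigma <= 0 at mu = %.4g L/min inside its valid range [%g, %g]",
      device_id, bad, valid_range[1], valid_range[2]
    ))
  }
  cal
}

eval_poly <- function(coefficients, x) {
  # Horner evaluation, coefficients ascending.
  out <- rep(0, length(x))
  for (ci in rev(coefficients)) out <- out * x + ci
  out
}

#' @export
print.device_calibration <- function(x, ...) {
  terms <- paste0(
    formatC(x$coefficients, digits = 6, format = "g"),
    c("", " mu", " mu^2", " mu^3")[seq_along(x$coefficients)]
  )
  cat(sprintf("<device_calibration> %s\n", x$device_id))
  cat("  sigma(mu) =", paste(terms, collapse = " + "), "\n")
  cat(sprintf("  valid for mu in [%g, %g] L/min\n",
              x$valid_range[1], x$valid_range[2]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Evaluate a device's error sigma at a measured VO2 level
#'
#' @param cal A [device_calibration()].
#' @param mu Measured VO2 in L/min; must be positive. Values outside the
#'   calibration's valid range but inside the physiologic envelope
#'   (0.3 to 6 L/min) are extrapolated with a warning; values outside the
#'   envelope are an error.
#' @return The error standard deviation sigma (L/min) at `mu`.
#' @export
sigma_at <- function(cal, mu) {
  stopifnot(inherits(cal, "device_calibration"))
  check_scalar_number(mu, "mu", positive = TRUE)
  if (mu < VO2_ENVELOPE[1] || mu > VO2_ENVELOPE[2]) {
    abort_range(sprintf(
      "mu = %g L/min is outside the supported physiologic envelope [%g, %g] L/min",
      mu, VO2_ENVELOPE[1], VO2_ENVELOPE[2]
    ))
  }
  if (mu < cal$valid_range[1] || mu > cal$valid_range[2]) {
    warning(sprintf(
      "mu = %g L/min is outside the '%s' calibration range [%g, %g]; extrapolating",
      mu, cal$device_id, cal$valid_range[1], cal$valid_range[2]
    ), call. = FALSE)
  }
  sigma <- eval_poly(cal$coefficients, mu)
  if (sigma <= 0) {
    abort_calibration_domain(sprintf(
      "calibration '%s' yields sigma = %g <= 0 at mu = %g L/min",
      cal$device_id, sigma, mu
    ))
  }
  sigma
}

#' Turn a VO2 value into its measurement-error distribution
#'
#' Combines a user-supplied VO2 value with the device's sigma(mu) calibration
#' to give the normal distribution modelling that measurement's day-to-day
#' error.
#'
#' @param mu Measured VO2 in L/min; positive.
#' @param device_id Device label; must exist in `registry`.
#' @param registry A calibration registry, by default the shipped one
#'   ([default_registry()]).
#' @return An object of class `measurement_distribution` with fields `mu`,
#'   `sigma`, `device_id`.
#' @export
make_distribution <- function(mu, device_id = "parvo_2400",
                              registry = default_registry()) {
  cal <- registry_lookup(registry, device_id)
  structure(
    list(mu = mu, sigma = sigma_at(cal, mu), device_id = device_id),
    class = "measurement_distribution"
  )
}

#' @export
print.measurement_distribution <- function(x, ...) {
  cat(sprintf("<measurement_distribution> Normal(mu = %g, sigma = %.4g) [%s]\n",
              x$mu, x$sigma, x$device_id))
  invisible(x)
}

#' Build a calibration registry
#'
#' @param ... [device_calibration()] objects.
#' @return A named list of calibrations, class `calibration_registry`.
#' @export
calibration_registry <- function(...) {
  cals <- list(...)
  if (!all(vapply(cals, inherits, logical(1), "device_calibration"))) {
    abort_invalid_input("all registry entries must be device_calibration objects")
  }
  names(cals) <- vapply(cals, `[[`, character(1), "device_id")
  if (anyDuplicated(names(cals))) {
    abort_invalid_input("duplicate device_id in registry")
  }
  structure(cals, class = "calibration_registry")
}

registry_lookup <- function(registry, device_id) {
  if (!inherits(registry, "calibration_registry")) {
    abort_invalid_input("`registry` must be a calibration_registry")
  }
  if (!is.character(device_id) || length(device_id) != 1L ||
      !device_id %in% names(registry)) {
    abort_lookup(sprintf(
      "unknown device '%s'; known devices: %s",
      as.character(device_id)[1], paste(names(registry), collapse = ", ")
    ))
  }
  registry[[device_id]]
}

#' @export
print.calibration_registry <- function(x, ...) {
  cat(sprintf("<calibration_registry> %d device(s)\n", length(x)))
  for (cal in x) print(cal)
  invisible(x)
}

#' Read / write a calibration registry file
#'
#' The registry file is JSON: an array of objects with fields `device_id`,
#' `coefficients` (ascending), `order`, `valid_range`, `provenance`.
#' Coefficients are serialized at full double precision (17 significant
#' digits), so a write/read round trip is exact.
#'
#' @param path File path.
#' @return `read_registry()` returns a `calibration_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("registry file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  cals <- lapply(raw, function(entry) {
    device_calibration(
      device_id = entry$device_id,
      coefficients = as.numeric(unlist(entry$coefficients)),
      valid_range = as.numeric(unlist(entry$valid_range)),
      provenance = if (is.null(entry$provenance)) "" else entry$provenance
    )
  })
  do.call(calibration_registry, cals)
}

#' @rdname read_registry
#' @param registry A `calibration_registry` to serialize.
#' @export
write_registry <- function(registry, path) {
  if (!inherits(registry, "calibration_registry")) {
    abort_invalid_input("`registry` must be a calibration_registry")
  }
  entries <- lapply(unname(registry), function(cal) {
    list(
      device_id = cal$device_id,
      coefficients = cal$coefficients,
      order = cal$order,
      valid_range = cal$valid_range,
      provenance = cal$provenance
    )
  })
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort_io(sprintf("directory does not exist: %s", dirname(path)))
  # digits = I(17): full double precision, so coefficients round-trip exactly
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
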