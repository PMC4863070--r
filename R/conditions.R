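# Classed conditions so callers (and the CLI) can distinguish failure modes.

vo2_abort <- function(message, class) {
  stop(structure(
    class = c(class, "vo2overlap_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_invalid_input <- function(message) vo2_abort(message, "vo2_invalid_input")
abort_calibration_domain <- function(message) vo2_abort(message, "vo2_calibration_domain")
abort_lookup <- function(message) vo2_abort(message, "vo2_lookup")
abort_range <- function(message) vo2_abort(message, "vo2_range")
abort_insufficient_data <- function(message) vo2_abort(message, "vo2_insufficient_data")
abort_recovery <- function(message) vo2_abort(message, "vo2_recovery")
abort_io <- function(message) vo2_abort(message, "vo2_io")
abort_parse <- function(message) vo2_abort(message, "vo2_parse")

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid_input(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_invalid_input(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}
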