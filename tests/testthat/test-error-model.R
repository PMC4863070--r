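test_that("sigma_at evaluates the calibration polynomial", {
  cal <- device_calibration("lin", c(0.05, 0.01), valid_range = c(1, 4))
  expect_equal(sigma_at(cal, 2.0), 0.07)
  # continuity / determinism on a grid
  grid <- seq(1, 4, by = 0.01)
  vals <- vapply(grid, function(m) sigma_at(cal, m), numeric(1))
  expect_equal(vals, 0.05 + 0.01 * grid)
  expect_identical(sigma_at(cal, 2.7), sigma_at(cal, 2.7))
})

test_that("sigma_at rejects bad inputs and domains", {
  cal <- device_calibration("lin", c(0.05, 0.01), valid_range = c(1, 4))
  expect_error(sigma_at(cal, 0), class = "vo2_invalid_input")
  expect_error(sigma_at(cal, -2), class = "vo2_invalid_input")
  # outside the physiologic envelope entirely
  expect_error(sigma_at(cal, 7), class = "vo2_range")
  expect_error(sigma_at(cal, 0.2), class = "vo2_range")
  # outside valid_range but inside the envelope: warn and extrapolate
  expect_warning(s <- sigma_at(cal, 0.5), "extrapolating")
  expect_equal(s, 0.055)
  # decreasing calibration whose extrapolation goes non-positive
  dec <- device_calibration("dec", c(0.10, -0.05), valid_range = c(1, 1.8))
  expect_error(
    suppressWarnings(sigma_at(dec, 2.5)),
    class = "vo2_calibration_domain"
  )
})

test_that("device_calibration enforces its invariants at construction", {
  expect_error(device_calibration("x", c(0.1)), class = "vo2_invalid_input")
  expect_error(device_calibration("x", rep(0.1, 5)), class = "vo2_invalid_input")
  expect_error(device_calibration("x", c(0.1, 0.01), valid_range = c(0, 4)),
               class = "vo2_invalid_input")
  expect_error(device_calibration("x", c(0.1, 0.01), valid_range = c(4, 1)),
               class = "vo2_invalid_input")
  # sigma non-positive inside the declared valid range
  expect_error(device_calibration("x", c(0.10, -0.05), valid_range = c(1, 4)),
               class = "vo2_calibration_domain")
})

test_that("make_distribution combines mu with the device calibration", {
  d <- make_distribution(1.5, "parvo_2400")
  expect_s3_class(d, "measurement_distribution")
  expect_identical(d$mu, 1.5)       # no internal rounding
  # sigma from the recovered linear ParvoMedics calibration (~0.06 L/min,
  # cf. the equal-variance inversion of the low-flow worked example)
  expect_equal(d$sigma, 0.0587, tolerance = 1e-2)
  expect_equal(d$sigma, sigma_at(default_registry()[["parvo_2400"]], 1.5))

  d2 <- make_distribution(3.3, "douglas_bag")
  expect_identical(d2$mu, 3.3)
  expect_gt(d2$sigma, sigma_at(default_registry()[["douglas_bag"]], 1.5))

  expect_error(make_distribution(1.5, "cosmed_k5"), class = "vo2_lookup")
  expect_error(make_distribution(1.5, "cosmed_k5"),
               regexp = "parvo_2400.*douglas_bag|douglas_bag.*parvo_2400")
})

test_that("shipped default calibrations are positive over their range and grow with flow", {
  reg <- default_registry()
  grid <- seq(1, 4, by = 0.01)
  for (dev in c("parvo_2400", "douglas_bag")) {
    sig <- vapply(grid, function(m) sigma_at(reg[[dev]], m), numeric(1))
    expect_true(all(sig > 0))
  }
  # ParvoMedics is linear with positive slope: non-decreasing everywhere
  p <- vapply(seq(1.5, 3.5, by = 0.05),
              function(m) sigma_at(reg[["parvo_2400"]], m), numeric(1))
  expect_true(all(diff(p) >= 0))
  # Douglas bag grows across the printed example span
  d <- reg[["douglas_bag"]]
  expect_lt(sigma_at(d, 1.5), sigma_at(d, 2.19))
  expect_lt(sigma_at(d, 2.19), sigma_at(d, 3.0))
  expect_lt(sigma_at(d, 3.0), sigma_at(d, 3.3))
})

test_that("registry files round-trip coefficients exactly", {
  reg <- calibration_registry(
    device_calibration("devA", c(0.019151010203040506, 0.026376212223242526),
                       valid_range = c(1, 4), provenance = "round-trip test"),
    device_calibration("devB", c(-0.02, 0.036, 0.023, -0.006),
                       valid_range = c(1.2, 3.9))
  )
  path <- tempfile(fileext = ".json")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_identical(names(back), c("devA", "devB"))
  expect_identical(back[["devA"]]$coefficients, reg[["devA"]]$coefficients)
  expect_identical(back[["devB"]]$coefficients, reg[["devB"]]$coefficients)
  expect_identical(back[["devB"]]$valid_range, reg[["devB"]]$valid_range)
  expect_identical(back[["devA"]]$provenance, "round-trip test")

  expect_error(read_registry(tempfile()), class = "vo2_io")
  expect_error(write_registry(reg, file.path(tempfile(), "x.json")),
               class = "vo2_io")
})
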