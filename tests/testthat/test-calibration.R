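test_that("test_retest_records reduces pairs to mean and n-1 SD", {
  rec <- test_retest_records(c(2.0, 3.1), c(2.2, 2.9), subject_id = c("a", "b"))
  expect_equal(rec$mean_vo2, c(2.1, 3.0))
  expect_equal(rec$sd_vo2, c(0.2, 0.2) / sqrt(2))
  expect_equal(rec$sd_vo2[1], sd(c(2.0, 2.2)))
  expect_error(test_retest_records(c(1, 2), c(1)), class = "vo2_invalid_input")
  expect_error(test_retest_records(numeric(0), numeric(0)),
               class = "vo2_invalid_input")
  expect_error(test_retest_records(c(1, -2), c(1, 2)), class = "vo2_invalid_input")
})

test_that("calibration CSV reader accepts both dialects", {
  f1 <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "s1", workload = "w1",
                       day1_vo2 = 2.0, day2_vo2 = 2.2),
            f1, row.names = FALSE)
  r1 <- read_calibration_csv(f1)
  expect_equal(r1$mean_vo2, 2.1)
  expect_equal(r1$sd_vo2, sd(c(2.0, 2.2)))

  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(mean_vo2 = c(2.1, 3.0), sd_vo2 = c(0.1, 0.2)),
            f2, row.names = FALSE)
  r2 <- read_calibration_csv(f2)
  expect_equal(r2$mean_vo2, c(2.1, 3.0))

  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(foo = 1), f3, row.names = FALSE)
  expect_error(read_calibration_csv(f3), class = "vo2_parse")
  expect_error(read_calibration_csv(tempfile()), class = "vo2_io")
})

test_that("fit_calibration interpolates noiseless polynomial data exactly", {
  truth <- c(0.02, 0.01, 0.005)
  rec <- noiseless_records(truth)
  cal <- fit_calibration(rec, "exact_dev", order = 2)
  expect_equal(cal$coefficients, truth, tolerance = 1e-10)
  expect_lt(attr(cal, "rss"), 1e-20)
  # cubic truth, cubic fit
  truth3 <- c(0.02, 0.015, 0.004, 0.001)
  cal3 <- fit_calibration(noiseless_records(truth3), "exact3", order = 3)
  expect_equal(cal3$coefficients, truth3, tolerance = 1e-10)
})

test_that("fit_calibration rejects underdetermined or degenerate input", {
  rec <- noiseless_records(c(0.02, 0.01, 0.005), mus = c(1, 2, 3))
  expect_error(fit_calibration(rec, "d", order = 3),
               class = "vo2_insufficient_data")
  same_mu <- data.frame(mean_vo2 = rep(2, 6), sd_vo2 = rep(0.1, 6))
  expect_error(fit_calibration(same_mu, "d", order = 2),
               class = "vo2_insufficient_data")
  expect_error(fit_calibration(noiseless_records(c(0.1, 0.01)), "d", order = 4),
               class = "vo2_invalid_input")
})

test_that("the c4 option rescales pair SDs to unbiased sigma estimates", {
  rec <- noiseless_records(c(0.02, 0.01, 0.005))
  plain <- fit_calibration(rec, "d", order = 2)
  corrected <- fit_calibration(rec, "d", order = 2, unbiased = TRUE)
  expect_equal(corrected$coefficients, plain$coefficients / sqrt(2 / pi),
               tolerance = 1e-10)
})

test_that("fit_calibration recovers the generating sigma curve from synthetic pairs", {
  truth <- c(0.02, 0.015, 0.004, 0.001) # gentle cubic, sigma ~0.04-0.17 L/min
  proto <- synthetic_protocol(
    workload_mus = seq(1.0, 4.0, length.out = 10),
    n_subjects = 50, # 500 pairs
    noise_coefficients = truth,
    seed = 2016
  )
  rec <- generate_test_retest(proto)
  cal <- fit_calibration(rec, "synth", order = 3, unbiased = TRUE)
  # central 80% of the design mu range; the 0.25 bound is the empirical
  # envelope of the max pointwise relative error across seeded replicates
  # (its median is ~0.09) and guards against gross estimator regressions
  grid <- seq(1.3, 3.7, length.out = 100)
  rel <- abs(vo2overlap:::eval_poly(cal$coefficients, grid) -
               vo2overlap:::eval_poly(truth, grid)) /
    vo2overlap:::eval_poly(truth, grid)
  expect_lt(max(rel), 0.25)
})

test_that("median recovery error stays below 10% across replicates", {
  truth <- c(0.02, 0.015, 0.004, 0.001)
  grid <- seq(1.3, 3.7, length.out = 60)
  sigma_true <- vo2overlap:::eval_poly(truth, grid)
  max_rel <- vapply(1:20, function(seed) {
    proto <- synthetic_protocol(
      workload_mus = seq(1.0, 4.0, length.out = 10),
      n_subjects = 50, noise_coefficients = truth, seed = seed
    )
    cal <- fit_calibration(generate_test_retest(proto), "synth",
                           order = 3, unbiased = TRUE)
    max(abs(vo2overlap:::eval_poly(cal$coefficients, grid) - sigma_true) / sigma_true)
  }, numeric(1))
  expect_lt(median(max_rel), 0.10)
})

test_that("default-calibration recovery reproduces its constraints and is deterministic", {
  reg1 <- recover_default_calibrations()
  reg2 <- recover_default_calibrations()
  expect_identical(reg1[["parvo_2400"]]$coefficients,
                   reg2[["parvo_2400"]]$coefficients)
  expect_identical(reg1[["douglas_bag"]]$coefficients,
                   reg2[["douglas_bag"]]$coefficients)
  # Parvo: exact solve
  expect_lt(max(abs(attr(reg1, "parvo_residuals"))), 1e-6)
  # Douglas: least-squares residual bound
  expect_lt(attr(reg1, "douglas_rmse"), 0.03)
  # round-trip every fitted constraint through the overlap function
  con <- worked_example_constraints()
  fit_con <- con[!con$holdout, ]
  for (i in seq_len(nrow(fit_con))) {
    row <- fit_con[i, ]
    got <- ovl_normal(
      row$mu_a, sigma_at(reg1[[row$device_a]], row$mu_a),
      row$mu_b, sigma_at(reg1[[row$device_b]], row$mu_b)
    )
    tol <- if (row$device_a == "parvo_2400") 1e-6 else 0.03
    expect_equal(got, row$target_ovl, tolerance = tol)
  }
})

test_that("recovery fails loudly when the constraint set is underdetermined", {
  con <- worked_example_constraints()
  missing_parvo <- con[-1, ]
  expect_error(recover_default_calibrations(missing_parvo),
               class = "vo2_recovery")
  no_douglas <- con[con$device_a == "parvo_2400", ]
  expect_error(recover_default_calibrations(no_douglas),
               class = "vo2_recovery")
  bad <- con
  bad$target_ovl[1] <- 1.5
  expect_error(recover_default_calibrations(bad), class = "vo2_invalid_input")
})
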