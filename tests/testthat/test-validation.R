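test_that("measured-current fixture loads and matches the published table", {
  rec <- measured_currents()
  expect_equal(nrow(rec), 4)
  expect_equal(rec$I_measured_A[rec$code == "1V_20Hz"], 0.012)
  expect_equal(rec$I_measured_A[rec$code == "5V_7.9Hz"], 0.069)
})

test_that("voltage scaling factors from the measured currents", {
  rec <- measured_currents()
  expect_equal(voltage_scaling_factor(rec, 1, 5, 20), 0.067 / 0.012)
  expect_equal(signif(voltage_scaling_factor(rec, 1, 5, 20), 2), 5.6)
  expect_equal(voltage_scaling_factor(rec, 1, 5, 7.9), 5.75)
  expect_error(voltage_scaling_factor(rec, 1, 3, 20), "incomplete data")
  same <- data.frame(code = c("a", "b"), voltage_V = c(1, 5),
                     frequency_Hz = 20, I_measured_A = c(0.01, 0.01))
  expect_equal(voltage_scaling_factor(same, 1, 5, 20), 1.0)
})

test_that("scaling factor of exactly linear records equals the voltage ratio", {
  r0 <- 0.0123
  volts <- c(0.5, 1, 2, 5, 8)
  rec <- data.frame(code = paste0("s", seq_along(volts)), voltage_V = volts,
                    frequency_Hz = 20, I_measured_A = r0 * volts)
  for (k in 2:length(volts)) {
    expect_equal(voltage_scaling_factor(rec, volts[1], volts[k], 20),
                 volts[k] / volts[1])
  }
})

test_that("prediction ratio divides measured by predicted", {
  expect_equal(prediction_ratio(0.012, 0.0077), 1.558, tolerance = 1e-3)
  expect_equal(prediction_ratio(0.067, 0.0385), 1.740, tolerance = 1e-3)
  expect_equal(prediction_ratio(0.5, 0.5), 1.0)
  expect_error(prediction_ratio(0.1, 0), "division error")
})

test_that("validation report merges measurements and raises the linearity flag", {
  g <- default_chamber()
  f <- cached_field(3e-4)
  rep <- build_validation_report(g, f, default_settings(),
                                 measured_currents())
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$table), 4)
  # measured 5.58/5.75 vs ideal 5 deviates by more than 5% -> flagged
  expect_true(rep$linearity_flag)
  expect_equal(rep$scaling$ideal, rep(5, 2))
  # measured exceeds predicted at every setting
  expect_true(all(rep$table$ratio > 1))
})

test_that("perfectly linear synthetic records raise no flag", {
  g <- default_chamber()
  f <- cached_field(3e-4)
  rec <- measured_currents()
  rec$I_measured_A <- 0.01 * rec$voltage_V  # exactly ohmic
  rep <- build_validation_report(g, f, default_settings(), rec)
  expect_false(rep$linearity_flag)
  expect_true(all(abs(rep$scaling$factor - rep$scaling$ideal) < 1e-12))
})

test_that("report without measurements contains predictions only", {
  g <- default_chamber()
  f <- cached_field(3e-4)
  rep <- build_validation_report(g, f, default_settings(), NULL)
  expect_true(all(is.na(rep$table$I_measured_A)))
  expect_false(rep$linearity_flag)
  expect_null(rep$scaling)
  # predictions scale linearly with setting voltage
  i <- rep$table$I_predicted_A[order(rep$table$voltage_V)]
  v <- sort(rep$table$voltage_V)
  expect_equal(i / v, rep(i[1] / v[1], 4))
})

test_that("the report is invariant to measurement record order", {
  g <- default_chamber()
  f <- cached_field(3e-4)
  rec <- measured_currents()
  rep1 <- build_validation_report(g, f, default_settings(), rec)
  rep2 <- build_validation_report(g, f, default_settings(),
                                  rec[rev(seq_len(nrow(rec))), ])
  expect_equal(rep1$table, rep2$table)
  expect_equal(rep1$scaling, rep2$scaling)
})
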