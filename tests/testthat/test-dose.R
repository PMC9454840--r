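test_that("duty cycles of the documented settings", {
  expect_equal(duty_cycle(pulse_waveform(1, 20, 3.6e-3)), 0.072)
  expect_equal(duty_cycle(pulse_waveform(1, 7.9, 10e-3)), 0.079)
  expect_equal(duty_cycle(pulse_waveform(1, 50, 1 / 50)), 1.0)
  expect_error(pulse_waveform(1, 20, 60e-3), "invalid waveform")
  expect_error(pulse_waveform(-1, 20, 3.6e-3), "invalid waveform")
})

test_that("sampled waveform is symmetric biphasic with the right duty", {
  wf <- pulse_waveform(1, 20, 3.6e-3)
  s <- sample_waveform(wf, 1e5, 1)
  expect_equal(max(s$voltage), 1)
  expect_equal(min(s$voltage), -1)
  expect_lt(abs(mean(s$voltage)), 1e-9)
  wf2 <- pulse_waveform(5, 7.9, 10e-3)
  s2 <- sample_waveform(wf2, 1e5, 10)
  expect_equal(mean(s2$voltage != 0), 0.079, tolerance = 1e-3)
  s0 <- sample_waveform(pulse_waveform(0, 20, 3.6e-3), 1e5, 2)
  expect_true(all(s0$voltage == 0))
  expect_error(sample_waveform(wf, 100, 1), "sample_rate")
})

test_that("closed-form average power matches waveform integration", {
  # oracle: P = mean over time of v(t) * i(t), with i(t) = v(t) * I / V
  cases <- list(list(v = 5, f = 7.9, tau = 10e-3, i = 0.0385),
                list(v = 5, f = 20, tau = 3.6e-3, i = 0.0385),
                list(v = 1, f = 20, tau = 3.6e-3, i = 0.012))
  for (cs in cases) {
    wf <- pulse_waveform(cs$v, cs$f, cs$tau)
    s <- sample_waveform(wf, 1e5, 10)
    p_num <- mean(s$voltage^2) * cs$i / cs$v
    expect_equal(average_power(wf, cs$i), p_num, tolerance = 5e-3)
  }
  expect_equal(average_power(pulse_waveform(5, 7.9, 10e-3), 0.0385),
               5 * 0.0385 * 0.079)
  expect_equal(average_power(pulse_waveform(5, 7.9, 10e-3), 0), 0)
  expect_equal(average_power(pulse_waveform(1, 10, 0.1), 1), 1)
})

test_that("deposited energy over the 10 min protocol", {
  wf79 <- pulse_waveform(5, 7.9, 10e-3)
  wf20 <- pulse_waveform(5, 20, 3.6e-3)
  # trapezoidal integration of the sampled instantaneous power as oracle
  s <- sample_waveform(wf79, 1e5, 79)  # 10 s of signal
  p_trace <- s$voltage^2 * (0.0385 / 5)
  e10 <- trapz_oracle(s$time, p_trace)
  expect_equal(deposited_energy(wf79, 0.0385, 10), e10, tolerance = 5e-3)
  expect_equal(deposited_energy(wf79, 0.0385, 600), 9.1245, tolerance = 1e-4)
  expect_equal(deposited_energy(wf20, 0.0385, 600), 8.316, tolerance = 1e-4)
  expect_equal(deposited_energy(wf79, 0.0385, 0), 0)
})

test_that("energy is additive over stimulation intervals", {
  wf <- pulse_waveform(5, 7.9, 10e-3)
  t1 <- 123.4; t2 <- 476.6
  expect_equal(deposited_energy(wf, 0.05, t1) + deposited_energy(wf, 0.05, t2),
               deposited_energy(wf, 0.05, t1 + t2))
})

test_that("adiabatic temperature bound exceeds the observed 5 V rises", {
  dt <- adiabatic_temp_rise(9.1, 1e-6, 1000, 4184)
  expect_equal(dt, 2.175, tolerance = 1e-3)
  # must bound the measured 1.4-1.6 K rises at 5 V
  expect_gte(dt, 1.6)
  expect_equal(adiabatic_temp_rise(0, 1e-6), 0)
})

test_that("dose table has control plus one consistent row per setting", {
  g <- default_chamber()
  f <- cached_field(3e-4)
  tab <- dose_table(g, default_settings(), f,
                    measurements = measured_currents())
  expect_equal(nrow(tab), 5)
  expect_equal(tab$code[1], "Control")
  r1 <- tab[tab$code == "1V_20Hz", ]
  r5 <- tab[tab$code == "5V_20Hz", ]
  # electrical linearity: every 5 V quantity is exactly 5x the 1 V row
  expect_equal(r5$I_theory_A, 5 * r1$I_theory_A)
  expect_equal(r5$field_V_per_m, 5 * r1$field_V_per_m)
  expect_equal(r5$P_avg_W, 25 * r1$P_avg_W)  # power scales as V * I
  # theoretical currents near the 2D-model predictions at 1.3 S/m
  expect_equal(r1$I_theory_A, 0.0077, tolerance = 0.05)
  expect_equal(r5$I_theory_A, 0.0385, tolerance = 0.05)
  # measured values merged by code
  expect_equal(r5$I_measured_A, 0.067)
  expect_true(is.na(tab$I_measured_A[tab$code == "Control"]))
  # energy consistency: E = P * duration
  expect_equal(tab$E_J, tab$P_avg_W * attr(tab, "duration_s"))
})

test_that("dose table warns on unknown measurement codes and handles empties", {
  g <- default_chamber()
  f <- cached_field(3e-4)
  meas <- data.frame(code = c("1V_20Hz", "9V_1Hz"),
                     I_measured_A = c(0.012, 0.1))
  expect_warning(tab <- dose_table(g, default_settings(), f, meas),
                 "unknown setting code")
  expect_equal(tab$I_measured_A[tab$code == "1V_20Hz"], 0.012)
  empty <- dose_table(g, list(), f)
  expect_equal(nrow(empty), 1)
  expect_equal(empty$code, "Control")
})
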