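test_that("noise-free traces are exactly scaled ideal waveforms", {
  wf <- pulse_waveform(1, 20, 3.6e-3)
  trace <- synth_current_trace(wf, 0.012, 0, 1e5, 5, seed = 7)
  expect_equal(max(abs(trace$current)), 0.012)
  shape <- sample_waveform(pulse_waveform(1, 20, 3.6e-3), 1e5, 5)
  expect_equal(trace$current, shape$voltage * 0.012)
  expect_equal(detect_peak_current(trace), 0.012)
})

test_that("traces are reproducible per seed and differ across seeds", {
  wf <- pulse_waveform(1, 20, 3.6e-3)
  t1 <- synth_current_trace(wf, 0.012, 5e-4, 1e5, 3, seed = 42)
  t2 <- synth_current_trace(wf, 0.012, 5e-4, 1e5, 3, seed = 42)
  t3 <- synth_current_trace(wf, 0.012, 5e-4, 1e5, 3, seed = 43)
  expect_identical(t1$current, t2$current)
  expect_false(identical(t1$current, t3$current))
})

test_that("trace generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(synth_current_trace(pulse_waveform(1, 20, 3.6e-3),
                                0.012, 5e-4, 1e5, 2, seed = 9))
  expect_identical(runif(1), before)
})

test_that("peak detection recovers the generator peak within 2% at 5% noise", {
  wf <- pulse_waveform(1, 20, 3.6e-3)
  peak <- 0.012
  for (seed in 1:10) {
    trace <- synth_current_trace(wf, peak, 0.05 * peak, 1e5, 20, seed = seed)
    est <- detect_peak_current(trace)
    expect_lt(abs(est - peak) / peak, 0.02)
  }
})

test_that("peak detection on pure noise stays within the noise scale", {
  wf <- pulse_waveform(1, 20, 3.6e-3)
  sd_n <- 5e-4
  for (seed in 1:5) {
    trace <- synth_current_trace(wf, 0, sd_n, 1e5, 10, seed = seed)
    expect_lte(detect_peak_current(trace), 4 * sd_n)
  }
  expect_equal(detect_peak_current(list(current = numeric(10))), 0)
  expect_error(detect_peak_current(list(current = numeric(0))), "empty")
})

test_that("perturbed geometries are reproducible and respect invariants", {
  base <- default_chamber()
  same <- perturbed_geometries(base, 0, 5, seed = 1)
  expect_length(same, 5)
  for (g in same) expect_equal(g$electrode_gap, base$electrode_gap)
  a <- perturbed_geometries(base, 0.05, 10, seed = 2)
  b <- perturbed_geometries(base, 0.05, 10, seed = 2)
  expect_equal(a, b)
  for (g in a) {
    expect_s3_class(validate_chamber_geometry(g), "chamber_geometry")
    expect_false(isTRUE(all.equal(g$electrode_gap, base$electrode_gap)))
  }
  expect_error(perturbed_geometries(base, 0.5, 2, seed = 1))
})

test_that("field spread under small geometry jitter tracks the gap jitter", {
  # E ~ V/d locally, so a 5% relative gap jitter should keep the
  # midpoint field within ~10% of the base value
  base <- default_chamber()
  e_base <- field_at(cached_field(5e-4), cbind(0, 0))$e_mag
  geoms <- perturbed_geometries(base, 0.05, 6, seed = 3)
  for (g in geoms) {
    f <- solve_potential(generate_mesh(g, 5e-4), 1)
    e <- field_at(f, cbind(0, 0))$e_mag
    expect_lt(abs(e - e_base) / e_base, 0.15)
  }
})

test_that("trace CSV round-trips with its sidecar metadata", {
  wf <- pulse_waveform(1, 20, 3.6e-3)
  trace <- synth_current_trace(wf, 0.012, 1e-4, 2e4, 2, seed = 5)
  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_trace_csv(trace, path)
  back <- read.csv(path)
  expect_equal(back$I_A, trace$current)
  expect_true(file.exists(paste0(path, ".meta.txt")))
})
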