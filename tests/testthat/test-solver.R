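test_that("the solver reproduces the closed-form parallel-plate solution", {
  mesh <- parallel_plate_mesh(1, 1, 0.2)
  field <- solve_potential(mesh, 1)
  # exact linear ramp phi = x * V / d is in the P1 space
  expect_equal(field$phi, mesh$nodes[, 1], tolerance = 1e-12)
  emag <- sqrt(field$efield[, 1]^2 + field$efield[, 2]^2)
  expect_equal(emag, rep(1, nrow(mesh$triangles)), tolerance = 1e-10)
  expect_equal(max(abs(field$efield[, 2])), 0, tolerance = 1e-10)
  # and the per-depth current is sigma * (V/d) * W = 1 A/m
  i2d <- electrode_current_per_depth(field, 1)
  expect_equal(i2d$current_per_depth, 1, tolerance = 1e-10)
})

test_that("zero applied voltage gives the zero field", {
  mesh <- parallel_plate_mesh(1, 1, 0.25)
  field <- solve_potential(mesh, 0)
  expect_true(all(field$phi == 0))
  expect_true(all(field$efield == 0))
})

test_that("a mesh without electrode tags is rejected", {
  mesh <- parallel_plate_mesh(1, 1, 0.25)
  mesh$boundary_edges$tag[mesh$boundary_edges$tag == "electrode_pos"] <- "wall"
  expect_error(solve_potential(mesh, 1), "configuration error")
})

test_that("the discrete solution obeys the maximum principle", {
  for (field in list(cached_field(4e-4), solve_potential(parallel_plate_mesh(1, 0.5, 0.2), 3))) {
    v2 <- field$voltage_difference / 2
    expect_lte(max(field$phi), v2 + 1e-9 * abs(v2))
    expect_gte(min(field$phi), -v2 - 1e-9 * abs(v2))
  }
})

test_that("solutions are linear in voltage: re-solve equals rescale", {
  mesh <- generate_mesh(default_chamber(), 5e-4)
  f1 <- solve_potential(mesh, 1)
  f5 <- solve_potential(mesh, 5)
  scaled <- scale_to_voltage(f1, 5)
  expect_equal(f5$phi, scaled$phi, tolerance = 1e-10)
  expect_equal(f5$efield, scaled$efield, tolerance = 1e-10)
})

test_that("voltage rescaling is a group action", {
  f <- cached_field(4e-4)
  same <- scale_to_voltage(f, f$voltage_difference)
  expect_equal(same$phi, f$phi)
  back <- scale_to_voltage(scale_to_voltage(f, 2), 1)
  expect_equal(back$phi, f$phi, tolerance = 1e-14)
  expect_equal(back$efield, f$efield, tolerance = 1e-14)
  f0 <- solve_potential(parallel_plate_mesh(1, 1, 0.5), 0)
  expect_error(scale_to_voltage(f0, 5), "invalid scale")
})

test_that("electrode fluxes balance to well under 1%", {
  f <- cached_field(3e-4)
  i2d <- electrode_current_per_depth(f, 1)
  expect_lt(i2d$balance, 0.01)
})

test_that("the field is symmetric under reflection in both axes", {
  f <- cached_field(3e-4)
  xs <- seq(-4.5e-3, 4.5e-3, length.out = 7)
  ys <- seq(-5e-3, 5e-3, length.out = 7)
  pts <- as.matrix(expand.grid(xs, ys))
  e0 <- field_at(f, pts)$e_mag
  ex <- field_at(f, cbind(-pts[, 1], pts[, 2]))$e_mag
  ey <- field_at(f, cbind(pts[, 1], -pts[, 2]))$e_mag
  expect_lt(max(abs(ex - e0) / e0), 0.005)
  expect_lt(max(abs(ey - e0) / e0), 0.005)
})

test_that("current scales linearly in conductivity", {
  f <- cached_field(4e-4)
  i1 <- electrode_current_per_depth(f, 1)
  i2 <- electrode_current_per_depth(f, 2)
  expect_equal(i2$current_per_depth, 2 * i1$current_per_depth)
  # and total_current rescales from the solve conductivity
  expect_equal(total_current(i1, 3.4e-3, 2), total_current(i2, 3.4e-3))
  expect_equal(total_current(i1, 3.4e-3), i1$current_per_depth * 3.4e-3)
})

test_that("the analytic plate field is V over d", {
  expect_equal(analytic_plate_field(1, 0.011), 90.90909, tolerance = 1e-6)
  expect_equal(analytic_plate_field(5, 0.011), 454.5455, tolerance = 1e-6)
  expect_equal(analytic_plate_field(0, 0.011), 0)
  expect_error(analytic_plate_field(1, 0), "invalid geometry")
})

test_that("midpoint field is robust to mesh resolution", {
  # brackets the reference plateau across default and +/- 2x resolutions
  for (h in c(6e-4, 3e-4, 1.5e-4)) {
    mid <- field_at(cached_field(h), cbind(0, 0))$e_mag
    expect_gte(mid, 88)
    expect_lte(mid, 93)
  }
})
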