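test_that("sphere-skull surface normals are radial within 3 degrees", {
  tp <- build_targeting_phantom()
  for (pt in list(c(0, 0, 42), c(42, 0, 0), c(0, -42, 0),
                  c(29.7, 0, 29.7))) {
    n <- surface_normal(tp$skull_mask, pt, "outer")
    radial <- pt / sqrt(sum(pt^2))
    ang <- acos(min(1, abs(sum(n * radial)))) * 180 / pi
    expect_lt(ang, 3)
    expect_gt(sum(n * radial), 0)            # outward orientation
  }
  # inner surface: normal faces the cavity (inward)
  ni <- surface_normal(tp$skull_mask, c(0, 0, 38), "inner")
  expect_lt(acos(min(1, abs(ni[3]))) * 180 / pi, 3)
  expect_lt(ni[3], 0)
})

test_that("flat-slab normals are perpendicular to the slab faces", {
  dims <- c(30, 30, 30)
  slab <- array(FALSE, dims); slab[, , 12:16] <- TRUE
  grid <- volume_grid(slab)
  n <- surface_normal(grid, c(0, 0, voxel_to_world(grid, c(0, 0, 16))[3]),
                      "outer")
  expect_equal(abs(n), c(0, 0, 1), tolerance = 1e-6)
})

test_that("points far from the surface raise an off-surface error", {
  tp <- build_targeting_phantom()
  expect_error(surface_normal(tp$skull_mask, c(0, 0, 0), "outer"),
               "off-surface")
})

test_that("incidence angle matches the analytic sphere geometry within 3 degrees", {
  deg <- pi / 180
  for (tilt in c(0, 10, 20, 35)) {
    E <- c(0, 0, 42)
    traj <- c(sin(tilt * deg), 0, -cos(tilt * deg))
    tp <- build_targeting_phantom(focus = E + 25 * traj, trajectory = traj)
    expect_equal(tp$truth$incidence_deg, tilt, tolerance = 1e-6)
    ir <- incidence_refraction(tp$plan, NULL, tp$skull_mask)
    expect_lt(abs(ir$incidence_deg - tilt), 3)
    expect_true(ir$incidence_deg >= 0 && ir$incidence_deg <= 90)
    expect_true(ir$refraction_deg >= 0 && ir$refraction_deg <= 90)
  }
})

test_that("angles are unchanged when the geometry is rotated to another axis", {
  deg <- pi / 180
  # same 20-degree oblique approach, constructed around z and around x
  E1 <- c(0, 0, 42); t1 <- c(sin(20 * deg), 0, -cos(20 * deg))
  E2 <- c(42, 0, 0); t2 <- c(-cos(20 * deg), 0, sin(20 * deg))
  a1 <- incidence_refraction(build_targeting_phantom(focus = E1 + 25 * t1,
                                                     trajectory = t1)$plan,
                             NULL,
                             build_targeting_phantom(focus = E1 + 25 * t1,
                                                     trajectory = t1)$skull_mask)
  tp2 <- build_targeting_phantom(focus = E2 + 25 * t2, trajectory = t2)
  a2 <- incidence_refraction(tp2$plan, NULL, tp2$skull_mask)
  expect_lt(abs(a1$incidence_deg - a2$incidence_deg), 1.5)
})

test_that("trajectories missing the skull raise missed-skull", {
  dims <- c(30, 30, 30)
  slab <- array(FALSE, dims); slab[1:4, , ] <- TRUE
  plan <- target_plan(focus = c(10, 0, 0), trajectory = c(0, 0, -1))
  expect_error(incidence_refraction(plan, NULL, volume_grid(slab)),
               "missed-skull")
})

test_that("opening vector of an axis-aligned cylinder is the axis, COM its centre", {
  tp <- build_targeting_phantom(opening_semi_axes = c(2.5, 2.5, 12),
                                opening_axis = c(0, 0, 1))
  fit <- opening_vector_fit(tp$opening_mask)
  expect_true(fit$direction_defined)
  expect_equal(abs(fit$direction), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fit$com, tp$truth$center, tolerance = 0.2)
})

test_that("tilted opening direction is recovered within 2 degrees", {
  axis <- c(sin(pi / 6), 0, cos(pi / 6))          # 30 degrees in x-z
  tp <- build_targeting_phantom(opening_axis = axis,
                                opening_semi_axes = c(2.5, 2.5, 12))
  fit <- opening_vector_fit(tp$opening_mask)
  ang <- acos(min(1, abs(sum(fit$direction * axis)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("degenerate opening masks are handled", {
  dims <- c(10, 10, 10)
  expect_error(opening_vector_fit(array(FALSE, dims)), "empty-input")
  single <- array(FALSE, dims); single[4:6, 4:6, 5] <- TRUE
  fit <- opening_vector_fit(single)
  expect_false(fit$direction_defined)
  expect_equal(fit$n_slices, 1L)
  expect_length(fit$com, 3L)
})

test_that("shift decomposition is Pythagorean to 1e-10", {
  sh <- shift_decomposition(target_plan(c(0, 0, 0), c(0, 0, 1)), c(3, 0, 4))
  expect_equal(c(sh$total_mm, sh$lateral_mm, sh$axial_mm), c(5, 3, 4))
  sh0 <- shift_decomposition(target_plan(c(1, 2, 3), c(1, 0, 0)), c(1, 2, 3))
  expect_equal(c(sh0$total_mm, sh0$lateral_mm, sh0$axial_mm), c(0, 0, 0))
  withr::with_seed(13, {
    for (i in 1:200) {
      d <- rnorm(3, sd = 5)
      traj <- rnorm(3); traj <- traj / sqrt(sum(traj^2))
      sh <- shift_decomposition(target_plan(c(0, 0, 0), traj), d)
      expect_lt(abs(sh$total_mm^2 - sh$lateral_mm^2 - sh$axial_mm^2), 1e-10)
    }
  })
})

test_that("full targeting report recovers a known 3-4-5 displacement", {
  tp <- build_targeting_phantom(opening_offset = c(3, 0, 4),
                                opening_semi_axes = c(2.5, 2.5, 10))
  rep <- targeting_report(tp$plan, tp$opening_mask, tp$skull_mask)
  expect_equal(rep$total_mm, 5, tolerance = 0.2)
  expect_equal(rep$lateral_mm, 3, tolerance = 0.2)
  expect_equal(rep$axial_mm, 4, tolerance = 0.2)
})
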