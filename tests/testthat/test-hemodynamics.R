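test_that("Reynolds number follows the pipe-flow definition", {
  bl <- blood_properties()
  expect_equal(as.numeric(reynolds_number(bl, 0, 0.01)), 0)
  expect_true(attr(reynolds_number(bl, 0, 0.01), "laminar"))
  re <- reynolds_number(bl, 0.6, 0.01)
  expect_equal(as.numeric(re), 2120)
  expect_true(attr(re, "laminar"))
  expect_false(attr(reynolds_number(bl, 0.7, 0.01), "laminar"))
  expect_error(reynolds_number(bl, 0.5, 0), "length")
  expect_error(blood_properties(dynamic_viscosity = -1), "viscosity")
})

test_that("Poiseuille oracle reproduces its closed forms", {
  po <- poiseuille_oracle(0.005, 0.6)
  expect_equal(po$centerline_speed, 1.2)
  expect_equal(po$profile(0), 1.2)
  expect_equal(po$profile(0.005), 0)
  expect_equal(po$pressure_gradient, 576)
  expect_error(poiseuille_oracle(0, 0.6), "radius")
})

cyl_flow <- function() cached("cyl_flow", {
  cyl <- build_cylinder_mesh(5, 25, 1.5)
  list(mesh = cyl, flow = solve_flow(cyl))
})

test_that("straight-pipe solution matches the Poiseuille parabola", {
  fl <- cyl_flow()$flow
  po <- poiseuille_oracle(0.005, 0.6)
  prof <- fl$centerline_profile
  err <- max(abs(prof$speed_cm_s / 100 - po$profile(prof$r_mm / 1000)))
  expect_lt(err / po$centerline_speed, 0.05)   # pointwise, vs peak speed
})

test_that("discrete mass conservation holds at cross-sections", {
  fl <- cyl_flow()$flow
  expect_lt(fl$mass_balance$defect, 0.005)
  expect_equal(fl$mean_outlet_speed, fl$mean_mid_speed, tolerance = 0.005)
})

test_that("speed decreases monotonically from centerline to wall", {
  fl <- cyl_flow()$flow
  prof <- fl$centerline_profile
  # bin by radius ring (polar mesh: identical radii repeat around rings)
  rings <- split(prof$speed_cm_s, round(prof$r_mm, 6))
  ring_mean <- vapply(rings, mean, numeric(1))
  expect_true(all(diff(ring_mean[order(as.numeric(names(ring_mean)))]) < 0))
})

test_that("velocity field inherits the mirror symmetry of the lumen", {
  fl <- cyl_flow()$flow
  mesh <- cyl_flow()$mesh
  np <- mesh$info$points_per_level
  lev <- floor(length(mesh$info$x_levels) / 2)
  idx <- (lev - 1L) * np + seq_len(np)
  y <- mesh$nodes[idx, 2]; z <- mesh$nodes[idx, 3]
  sp <- sqrt(rowSums(fl$velocity[idx, ]^2))
  # pair each node with its y-mirror partner
  key <- paste(round(-y, 9), round(z, 9))
  partner <- match(key, paste(round(y, 9), round(z, 9)))
  ok <- !is.na(partner)
  expect_gt(mean(ok), 0.95)
  # symmetric up to the Picard tolerance and sparse-LU rounding
  expect_lt(max(abs(sp[ok] - sp[partner[ok]])) / max(sp), 1e-4)
})

test_that("profile error halves under mesh refinement", {
  po <- poiseuille_oracle(0.004, 0.6)
  errs <- vapply(c(3, 1.5), function(h) {
    fl <- solve_flow(build_cylinder_mesh(4, 16, h),
                     control = flow_control(tol = 1e-9))
    prof <- fl$centerline_profile
    max(abs(prof$speed_cm_s / 100 - po$profile(prof$r_mm / 1000))) /
      po$centerline_speed
  }, numeric(1))
  expect_lt(errs[2], 0.6 * errs[1])   # first order or better
})

test_that("the laminar guard refuses out-of-regime inputs unless overridden", {
  cyl <- build_cylinder_mesh(5, 10, 2.5)
  fastbc <- flow_bc(inlet_mean_velocity = 0.8)   # Re ~ 2827
  expect_error(solve_flow(cyl, bc = fastbc), "laminar")
  expect_warning(
    fl <- solve_flow(cyl, bc = fastbc,
                     control = flow_control(allow_high_re = TRUE)),
    "laminar")
  expect_true(fl$converged)
})

test_that("plug inlet remains available and conserves mass", {
  cyl <- build_cylinder_mesh(4, 12, 2)
  fl <- solve_flow(cyl, bc = flow_bc(inlet_mean_velocity = 0.3,
                                     profile = "plug"))
  expect_lt(fl$mass_balance$defect, 0.02)
})

test_that("flow errors are informative", {
  expect_error(solve_flow(build_box_mesh(10, 5, 5, 2.5)), "lumen")
})
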