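test_that("unloaded equilibrium is exactly the reference state", {
  sol <- solve_static(solid_mesh(small_mesh()), neo_hookean_material(),
                      linear_elastic_material(),
                      traction_load(force_magnitude = 0))
  expect_true(sol$converged)
  expect_equal(max(abs(sol$displacement)), 0)
  expect_equal(max(sol$von_mises_stress), 0, tolerance = 1e-9)
  expect_equal(sol$J, rep(1, length(sol$J)))
})

test_that("internal forces are the gradient of the strain energy", {
  # directional FD derivative of the assembled energy vs the residual, with
  # the nodal pressure at its eliminated value
  bm <- build_box_mesh(10, 6, 6, 2)
  mats <- etaplan:::solid_material_arrays(bm, neo_hookean_material(),
                                          linear_elastic_material())
  el <- matrix(as.integer(bm$elems), ncol = 4)
  nn <- nrow(bm$nodes)
  with_seed(1, {
    u0 <- matrix(rnorm(nn * 3, 0, 2e-4), nn, 3)
    s0 <- etaplan:::solid_system(bm$nodes, el, u0, numeric(nn), mats$c1,
                                 mats$kappa, mats$kloc, mats$nodal,
                                 FALSE, FALSE)
    kb <- ifelse(s0$has_pressure > 0, s0$kbar, 0)
    pn <- kb * (s0$Jbar - 1)
    s <- etaplan:::solid_system(bm$nodes, el, u0, pn, mats$c1, mats$kappa,
                                mats$kloc, mats$nodal, FALSE, FALSE)
    for (rep in 1:3) {
      d <- matrix(rnorm(nn * 3), nn, 3); d <- d / sqrt(sum(d^2))
      h <- 1e-7
      ep <- local({
        sp <- etaplan:::solid_system(bm$nodes, el, u0 + h * d, numeric(nn),
                                     mats$c1, mats$kappa, mats$kloc,
                                     mats$nodal, FALSE, FALSE)
        sp$energy
      })
      em <- local({
        sm_ <- etaplan:::solid_system(bm$nodes, el, u0 - h * d, numeric(nn),
                                      mats$c1, mats$kappa, mats$kloc,
                                      mats$nodal, FALSE, FALSE)
        sm_$energy
      })
      fd <- (ep - em) / (2 * h)
      an <- sum(s$grad * d)
      expect_equal(an, fd, tolerance = 1e-5)
    }
  })
})

test_that("uniaxial patch test matches FL/(EA) closed form", {
  bar <- build_box_mesh(40, 10, 10, 2.5, region = "artery_wall")
  art <- linear_elastic_material(youngs_modulus = 1e6, poisson_ratio = 0.3)
  tol <- 1e-9
  p0 <- function(col) which(abs(bar$nodes[, col]) < tol)
  Fload <- 0.5
  sol <- solve_static(
    bar, neo_hookean_material(), art,
    traction_load(force_magnitude = Fload, direction = c(1, 0, 0),
                  patch_tag = "fixed_end_B"),
    fixed_tags = character(0),
    extra_constraints = list(list(nodes = p0(1), comps = 1L),
                             list(nodes = p0(2), comps = 2L),
                             list(nodes = p0(3), comps = 3L)))
  tip <- mean(sol$displacement[etaplan:::nodes_of_tags(bar, "fixed_end_B"), 1])
  exact <- Fload * 0.04 / (art$youngs_modulus * 0.01 * 0.01)
  expect_equal(tip, exact, tolerance = 0.02)
})

test_that("sparse solver matches an independent dense-assembly Newton solver", {
  for (mesh in list(one_tet_mesh(), build_box_mesh(10, 5, 5, 5))) {
    mats <- etaplan:::solid_material_arrays(mesh, neo_hookean_material(),
                                            linear_elastic_material())
    ld <- traction_load(force_magnitude = 0.02, patch_tag =
                          if (identical(mesh$info$kind, "one_tet"))
                            "traction_patch" else "fixed_end_B",
                        direction = c(0.3, 0.2, 1))
    fixed_nodes <- etaplan:::nodes_of_tags(mesh, "fixed_end_A")
    sol <- solve_static(mesh, neo_hookean_material(),
                        linear_elastic_material(), ld,
                        fixed_tags = "fixed_end_A",
                        control = solid_control(tol = 1e-10))
    f_nodal <- etaplan:::traction_force_vector(mesh, ld)
    free <- setdiff(seq_len(3 * nrow(mesh$nodes)),
                    rep(3L * (fixed_nodes - 1L), each = 3) + 1:3)
    el <- matrix(as.integer(mesh$elems), ncol = 4)
    u_oracle <- dense_newton_solve(mesh$nodes, el, mats$c1, mats$kappa,
                                   mats$kloc, mats$nodal, f_nodal, free)
    expect_lt(max(abs(sol$displacement - u_oracle)), 1e-8)
  }
})

test_that("response is linear at small loads", {
  sm <- solid_mesh(small_mesh())
  d1 <- tissue_deformation_metric(
    solve_static(sm, neo_hookean_material(), linear_elastic_material(),
                 traction_load(force_magnitude = 0.005)))
  d2 <- tissue_deformation_metric(
    solve_static(sm, neo_hookean_material(), linear_elastic_material(),
                 traction_load(force_magnitude = 0.01)))
  expect_equal(as.numeric(d2) / as.numeric(d1), 2, tolerance = 0.01)
})

test_that("deformation grows with force; dilatation stays near one", {
  s1 <- small_solve(1)
  s2 <- small_solve(2)
  d1 <- as.numeric(tissue_deformation_metric(s1))
  d2 <- as.numeric(tissue_deformation_metric(s2))
  expect_gt(d2, d1)
  expect_gt(d1, 0)
  # nodal dilatation field of the mixed formulation stays nearly isochoric
  expect_lt(max(abs(s2$Jbar - 1)), 0.05)
  w1 <- as.numeric(artery_wall_stress(s1))
  w2 <- as.numeric(artery_wall_stress(s2))
  expect_gt(w2, w1)
})

test_that("deformation metric definition: patch mean of |u|", {
  sol <- small_solve(1)
  sm <- sol$mesh
  pn <- etaplan:::nodes_of_tags(sm, "traction_patch")
  manual <- mean(sqrt(rowSums(sol$displacement[pn, ]^2))) * 100
  expect_equal(as.numeric(tissue_deformation_metric(sol)), manual)
  # a synthetic uniform translation reports exactly its magnitude
  fake <- sol
  fake$displacement <- matrix(rep(c(3e-3, 0, 4e-3), each = nrow(sm$nodes)),
                              ncol = 3)
  expect_equal(as.numeric(tissue_deformation_metric(fake)), 0.5)
  expect_equal(attr(tissue_deformation_metric(fake), "max_tissue_cm"), 0.5)
})

test_that("solver reports errors for ill-posed setups", {
  sm <- solid_mesh(small_mesh())
  expect_error(solve_static(sm, neo_hookean_material(),
                            linear_elastic_material(),
                            traction_load(patch_tag = "no_such_tag")),
               "tag")
  bad <- small_solve(1)
  bad$converged <- FALSE
  expect_error(tissue_deformation_metric(bad), "converge")
  expect_error(artery_wall_stress(bad), "converge")
})

test_that("force sweep is consistent with single solves and monotone", {
  p <- small_params()
  tab <- cached("small_sweep", force_sweep(list(p), c(1, 2)))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$converged))
  expect_equal(tab$deformation_cm[1],
               as.numeric(tissue_deformation_metric(small_solve(1))),
               tolerance = 1e-10)
  expect_true(all(diff(tab$deformation_cm) > 0))
  expect_true(all(diff(tab$wall_stress_Pa) > 0))
  # CSV side channel
  f <- tempfile(fileext = ".csv")
  force_sweep(list(p), c(1), file = f)
  got <- utils::read.csv(f)
  expect_named(got, c("thickness_mm", "force_N", "deformation_cm",
                      "wall_stress_Pa"))
  # failed cells are flagged, sweep continues
  bad <- force_sweep(list(p), c(1e-9, 1))
  expect_true(any(!bad$converged) || all(bad$converged))
  expect_equal(nrow(bad), 2)
})
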