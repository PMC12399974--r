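test_that("geometry parameters are validated", {
  expect_s3_class(geometry_params(), "geometry_params")
  expect_error(geometry_params(tissue_thickness = -1), "geometry error")
  expect_error(geometry_params(artery_wall_thickness = 7), "geometry error")
  expect_error(geometry_params(traction_patch_width = 50), "patch")
  expect_error(geometry_params(lumen_length = 100), "lumen_length")
  expect_error(geometry_params(dissection_window = 99), "dissection_window")
})

test_that("meshes are well-posed over the study grid", {
  for (th in c(5, 10, 20)) {
    m <- build_tissue_artery_geometry(
      geometry_params(tissue_thickness = th, target_element_size = 3))
    v <- etaplan:::tet_volumes(m$nodes, m$elems)
    expect_gt(min(v), 0)
    expect_setequal(unique(m$boundary_tag),
                    c("fixed_end_A", "fixed_end_B", "traction_patch",
                      "inlet", "outlet", "fsi_wall", "free_surface"))
    expect_setequal(unique(m$region), c("tissue", "artery_wall", "lumen"))
    # tag partition: every boundary facet carries exactly one tag
    expect_equal(length(m$boundary_tag), nrow(m$boundary_faces))
  }
})

test_that("solid and lumen sub-meshes are conforming", {
  m <- small_mesh()
  for (sub in list(solid_mesh(m), lumen_mesh(m))) {
    tf <- etaplan:::tet_faces(sub$elems)
    mult <- etaplan:::face_multiplicity(tf$sorted)
    expect_true(all(mult %in% c(1L, 2L)))
  }
  # tissue and artery wall share faces node-for-node (single grid): there
  # are interior faces whose two parent tets lie in different regions
  sm <- solid_mesh(m)
  tf <- etaplan:::tet_faces(sm$elems)
  mult <- etaplan:::face_multiplicity(tf$sorted)
  key <- paste(tf$sorted[, 1], tf$sorted[, 2], tf$sorted[, 3])
  shared <- split(sm$region[tf$elem][mult == 2], key[mult == 2])
  n_interface <- sum(vapply(shared, function(r)
    length(unique(r)) == 2, logical(1)))
  expect_gt(n_interface, 0)
})

test_that("mesh resolution honours the target element size", {
  m <- small_mesh()
  h_req <- small_params()$target_element_size / 1000
  edge <- m$nodes[m$elems[, 2], ] - m$nodes[m$elems[, 1], ]
  med <- stats::median(sqrt(rowSums(edge^2)))
  expect_gt(med, h_req / 2)
  expect_lt(med, 2 * h_req * sqrt(3))
})

test_that("refinement scaling and monotonicity hold", {
  n_coarse <- nrow(build_tissue_artery_geometry(
    geometry_params(tissue_thickness = 10, target_element_size = 4))$elems)
  n_mid <- nrow(build_tissue_artery_geometry(
    geometry_params(tissue_thickness = 10, target_element_size = 3))$elems)
  n_fine <- nrow(build_tissue_artery_geometry(
    geometry_params(tissue_thickness = 10, target_element_size = 2))$elems)
  expect_gte(n_mid, n_coarse)      # monotone under refinement
  ratio <- n_fine / n_coarse       # halving h
  expect_gt(ratio, 4); expect_lt(ratio, 12)
})

test_that("mesh determinism: identical params give identical meshes", {
  p <- small_params()
  m1 <- build_tissue_artery_geometry(p)
  m2 <- build_tissue_artery_geometry(p)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$boundary_tag, m2$boundary_tag)
})

test_that("default-parameter mesh matches the reference model scale", {
  m <- cached("mesh_1mm", build_tissue_artery_geometry(
    geometry_params(tissue_thickness = 5)))
  n_solid <- sum(m$region != "lumen")
  # reference solid model: ~3e4 linear tets; order of magnitude only
  expect_gt(n_solid, 3e3)
  expect_lt(n_solid, 3e5)
  expect_gt(nrow(m$nodes), 7e3)
  expect_lt(nrow(m$nodes), 7e5)
})

test_that("mesh quality behaves like a radius ratio", {
  # regular tetrahedron scores exactly 1
  s <- 1 / sqrt(2)
  reg <- rbind(c(1, 0, -s), c(-1, 0, -s), c(0, 1, s), c(0, -1, s)) / 100
  mreg <- etaplan:::new_fsi_mesh(reg, matrix(1:4, 1), "tissue",
                                 matrix(c(1, 2, 3), 1), "free_surface", 0.01,
                                 list())
  expect_equal(as.numeric(mesh_quality(mreg)), 1, tolerance = 1e-12)
  # a flattened sliver scores < 0.1
  sliver <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 1e-3)) / 100
  msl <- etaplan:::new_fsi_mesh(sliver, matrix(1:4, 1), "tissue",
                                matrix(c(1, 2, 3), 1), "free_surface", 0.01,
                                list())
  expect_lt(as.numeric(mesh_quality(msl)), 0.1)
  # generated meshes stay good
  expect_gte(as.numeric(mesh_quality(small_mesh())), 0.5)
  expect_error(mesh_quality(etaplan:::new_fsi_mesh(
    reg, matrix(integer(0), 0, 4), character(0),
    matrix(integer(0), 0, 3), character(0), 0.01, list())), "empty")
})
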