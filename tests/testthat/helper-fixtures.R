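# Shared fixtures, built once per test run (meshes and solves are cached so
# independent test files can reuse them).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A reduced tissue-artery geometry: full physics, small footprint.
small_params <- function(h = 2.5)
  geometry_params(tissue_thickness = 6, slab_length = 30, slab_width = 30,
                  traction_patch_width = 8, traction_patch_length = 8,
                  traction_patch_offset = 10, target_element_size = h,
                  dissection_window = 12)

small_mesh <- function() cached("small_mesh",
                                build_tissue_artery_geometry(small_params()))

small_solve <- function(force) cached(
  sprintf("small_solve_%g", force),
  solve_static(solid_mesh(small_mesh()), neo_hookean_material(),
               linear_elastic_material(),
               traction_load(force_magnitude = force)))

# Single-tetrahedron mesh (unit-scale, metres/1000) with one fixed face and
# the opposite vertex region tagged for loading.
one_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0),
                 c(0, 0, 0.01))
  elems <- matrix(1:4, 1)
  bf <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  tags <- c("fixed_end_A", "free_surface", "free_surface", "traction_patch")
  etaplan:::new_fsi_mesh(nodes, elems, "tissue", bf, tags, 0.01,
                         info = list(kind = "one_tet"))
}

# Deterministic per-test RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}
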