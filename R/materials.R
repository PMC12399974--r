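# Constitutive models and loads.

#' Neo-Hookean soft-tissue material
#'
#' Compressible Neo-Hookean model with strain energy
#' `W = C1 (Ibar1 - 3) + (1/D1) (J - 1)^2`, where `Ibar1 = J^(-2/3) tr(F'F)`
#' is the isochoric first invariant and `J = det F`. The shear modulus is
#' `mu = 2 C1` and the bulk modulus `K = 2/D1`; the defaults describe
#' peri-thyroid soft tissue (nearly incompressible, `mu/K ~ 7e-4`).
#'
#' @param C1 Deviatoric constant, Pa.
#' @param D1 Volumetric compliance, 1/Pa.
#' @return An object of class `neo_hookean_material`.
#' @export
neo_hookean_material <- function(C1 = 5000, D1 = 1.4e-7) {
  if (!is.finite(C1) || C1 <= 0) stop("C1 must be > 0")
  if (!is.finite(D1) || D1 <= 0) stop("D1 must be > 0")
  m <- list(C1 = C1, D1 = D1, shear_modulus = 2 * C1, bulk_modulus = 2 / D1)
  if (m$shear_modulus / m$bulk_modulus > 0.1)
    warning("material is far from incompressible (mu/K = ",
            signif(m$shear_modulus / m$bulk_modulus, 3), ")")
  structure(m, class = "neo_hookean_material")
}

#' Linear elastic material (artery wall)
#'
#' Used for the stiff artery wall; inside the finite-strain solver it is
#' realized as a compressible Neo-Hookean solid with moduli matched to
#' `(E, nu)`, which coincides with linear elasticity at the sub-percent
#' strains the wall experiences.
#'
#' @param youngs_modulus Young's modulus, Pa.
#' @param poisson_ratio Poisson's ratio, in (0, 0.5).
#' @return An object of class `linear_elastic_material`.
#' @export
linear_elastic_material <- function(youngs_modulus = 5e6, poisson_ratio = 0.49) {
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0")
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must be in (0, 0.5)")
  E <- youngs_modulus; nu <- poisson_ratio
  structure(list(youngs_modulus = E, poisson_ratio = nu,
                 shear_modulus = E / (2 * (1 + nu)),
                 bulk_modulus = E / (3 * (1 - 2 * nu))),
            class = "linear_elastic_material")
}

#' Instrument traction load
#'
#' A total force applied as a uniform dead traction over the facets of a
#' boundary tag (force / tagged area). The default direction pulls the tissue
#' away from the artery (+z, outward normal of the top face).
#'
#' @param force_magnitude Total force, N (study values 0.5, 1, 2; capped at 10).
#' @param direction Load direction; normalized internally.
#' @param patch_tag Boundary tag carrying the traction.
#' @return An object of class `traction_load`.
#' @export
traction_load <- function(force_magnitude = 1, direction = c(0, 0, 1),
                          patch_tag = "traction_patch") {
  if (!is.finite(force_magnitude) || force_magnitude < 0 || force_magnitude > 10)
    stop("force_magnitude must be in [0, 10] N")
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  structure(list(force_magnitude = force_magnitude,
                 direction = direction / nd, patch_tag = patch_tag),
            class = "traction_load")
}

#' Neo-Hookean strain energy density
#'
#' Evaluates `W = C1 (Ibar1 - 3) + (1/D1) (J - 1)^2` for one deformation
#' gradient. Zero for any rigid-body deformation.
#'
#' @param deformation_gradient 3x3 matrix with positive determinant.
#' @param material A [neo_hookean_material()].
#' @return Strain energy density, Pa.
#' @export
strain_energy_density <- function(deformation_gradient, material) {
  F <- deformation_gradient
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)),
            inherits(material, "neo_hookean_material"))
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  I1 <- sum(F * F)
  material$C1 * (J^(-2 / 3) * I1 - 3) + (1 / material$D1) * (J - 1)^2
}
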