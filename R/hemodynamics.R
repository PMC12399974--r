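# Steady laminar incompressible flow in the innominate-artery lumen.

#' Blood properties
#'
#' @param density Blood density, kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity, Pa s.
#' @param body_force Body force per unit mass, N/kg (default none).
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1060, dynamic_viscosity = 0.003,
                             body_force = c(0, 0, 0)) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("dynamic_viscosity must be > 0")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity,
                 body_force = body_force),
            class = "blood_properties")
}

#' Flow boundary conditions
#'
#' Velocity inlet / pressure outlet, no-slip walls. The default inlet is the
#' fully developed parabolic profile at the given mean velocity: at the study
#' Reynolds number (~2100) the laminar entrance length is metres long, so a
#' plug inlet could never develop inside the 6-diameter lumen segment and the
#' mid-plane metric would measure an arbitrary truncation artifact; the
#' physiological upstream vessel is long. A plug profile remains available.
#'
#' @param inlet_mean_velocity Mean (bulk) inlet velocity, m/s.
#' @param outlet_pressure Outlet pressure, Pa.
#' @param profile `"parabolic"` (default) or `"plug"`.
#' @return An object of class `flow_bc`.
#' @export
flow_bc <- function(inlet_mean_velocity = 0.60, outlet_pressure = 0,
                    profile = c("parabolic", "plug")) {
  if (!is.finite(inlet_mean_velocity) || inlet_mean_velocity <= 0)
    stop("inlet velocity must be > 0")
  structure(list(inlet_mean_velocity = inlet_mean_velocity,
                 outlet_pressure = outlet_pressure,
                 profile = match.arg(profile)),
            class = "flow_bc")
}

#' Reynolds number
#'
#' `Re = rho v L / mu` with the lumen diameter as the characteristic length
#' (pipe-flow convention). Pipe flow is laminar below Re = 2300.
#'
#' @param blood A [blood_properties()].
#' @param speed Bulk speed, m/s (>= 0).
#' @param characteristic_length Characteristic length, m (> 0).
#' @return Reynolds number, with logical attribute `laminar`.
#' @export
reynolds_number <- function(blood, speed, characteristic_length) {
  stopifnot(inherits(blood, "blood_properties"))
  if (!is.finite(characteristic_length) || characteristic_length <= 0)
    stop("characteristic_length must be > 0")
  if (!is.finite(speed) || speed < 0) stop("speed must be >= 0")
  re <- blood$density * speed * characteristic_length / blood$dynamic_viscosity
  structure(re, laminar = re < 2300)
}

#' Poiseuille closed form (analytic oracle)
#'
#' Fully developed laminar pipe flow: `u(r) = 2 v_mean (1 - r^2/R^2)`,
#' pressure gradient `8 mu v_mean / R^2`.
#'
#' @param lumen_radius Pipe radius, m.
#' @param mean_velocity Bulk velocity, m/s.
#' @param blood A [blood_properties()].
#' @return List with `centerline_speed`, `profile` (function of r, m), and
#'   `pressure_gradient` (Pa/m).
#' @export
poiseuille_oracle <- function(lumen_radius, mean_velocity,
                              blood = blood_properties()) {
  if (!is.finite(lumen_radius) || lumen_radius <= 0) stop("radius must be > 0")
  R <- lumen_radius
  list(centerline_speed = 2 * mean_velocity,
       profile = function(r) 2 * mean_velocity * (1 - (r / R)^2),
       pressure_gradient = 8 * blood$dynamic_viscosity * mean_velocity / R^2)
}

#' Flow solver controls
#'
#' @param tol Relative velocity-change tolerance of the Picard iteration.
#' @param max_iter Maximum Picard iterations.
#' @param relax Under-relaxation factor on the velocity update.
#' @param convection Include the convective term (FALSE = Stokes flow).
#' @param allow_high_re Override the laminar-regime guard.
#' @export
flow_control <- function(tol = 1e-6, max_iter = 80, relax = 0.7,
                         convection = TRUE, allow_high_re = FALSE) {
  list(tol = tol, max_iter = max_iter, relax = relax,
       convection = convection, allow_high_re = allow_high_re)
}

# Distance of lumen nodes from the reference axis (y/z centre in info).
lumen_node_radius <- function(mesh, nodes = mesh$nodes) {
  ctr <- mesh$info$centre
  sqrt((nodes[, 2] - ctr[1])^2 + (nodes[, 3] - ctr[2])^2)
}

#' Solve steady incompressible flow in the lumen
#'
#' Equal-order P1/P1 finite elements with PSPG pressure stabilization;
#' Picard iteration on the convective term, initialized from the Stokes
#' solution and under-relaxed. Inlet velocity is imposed strongly, walls are
#' no-slip, the outlet is a (pressure) natural boundary.
#'
#' @param lumen A lumen `fsi_mesh` (from [lumen_mesh()] or
#'   [build_cylinder_mesh()]), possibly with morphed coordinates.
#' @param blood A [blood_properties()].
#' @param bc A [flow_bc()].
#' @param control See [flow_control()].
#' @return A `flow_solution`: `velocity` (n x 3, m/s), `pressure` (Pa),
#'   `mean_outlet_speed` and `mean_mid_speed` (cm/s), `centerline_profile`
#'   (data frame `r_mm`, `speed_cm_s`), mass-balance diagnostics, and
#'   convergence metadata.
#' @export
solve_flow <- function(lumen, blood = blood_properties(), bc = flow_bc(),
                       control = flow_control()) {
  stopifnot(inherits(lumen, "fsi_mesh"))
  if (!all(lumen$region == "lumen")) lumen <- lumen_mesh(lumen)
  for (tg in c("inlet", "outlet", "fsi_wall"))
    if (!any(lumen$boundary_tag == tg)) stop("lumen mesh lacks '", tg, "' tag")
  nn <- nrow(lumen$nodes)
  R <- lumen$info$radius
  re <- reynolds_number(blood, bc$inlet_mean_velocity, 2 * R)
  if (!attr(re, "laminar")) {
    if (!control$allow_high_re)
      stop("flow regime not laminar (Re = ", round(re),
           " >= 2300); set allow_high_re to override")
    warning("Re = ", round(re), " >= 2300: laminar model outside its regime")
  }

  inlet_nodes <- nodes_of_tags(lumen, "inlet")
  wall_nodes <- setdiff(nodes_of_tags(lumen, "fsi_wall"),
                        nodes_of_tags(lumen, c("inlet", "outlet")))
  rin <- lumen_node_radius(lumen)[inlet_nodes]
  uin <- if (bc$profile == "parabolic") {
    2 * bc$inlet_mean_velocity * pmax(0, 1 - (rin / R)^2)
  } else rep(bc$inlet_mean_velocity, length(inlet_nodes))
  uin[rin >= R * (1 - 1e-9)] <- 0   # rim nodes: no-slip wins

  ubc <- matrix(NA_real_, nn, 3)
  ubc[wall_nodes, ] <- 0
  ubc[inlet_nodes, ] <- cbind(uin, 0, 0)

  fixed_mask <- !is.na(ubc[, 1])
  vel_dof <- function(node, k) 3L * (node - 1L) + k
  fixed_dofs <- as.vector(vapply(1:3, function(k)
    vel_dof(which(fixed_mask), k), integer(sum(fixed_mask))))
  xfix <- numeric(4L * nn)
  for (k in 1:3) xfix[vel_dof(which(fixed_mask), k)] <- ubc[fixed_mask, k]
  all_dofs <- seq_len(4L * nn)
  freed <- setdiff(all_dofs, fixed_dofs)

  # outlet pressure natural term: rhs -= p_out * int_outlet v . n
  b0 <- numeric(4L * nn)
  if (bc$outlet_pressure != 0) {
    sel <- lumen$boundary_tag == "outlet"
    faces <- lumen$boundary_faces[sel, , drop = FALSE]
    ar <- face_areas(lumen$nodes, faces)
    for (f in seq_len(nrow(faces)))
      for (nd in faces[f, ])
        b0[vel_dof(nd, 1)] <- b0[vel_dof(nd, 1)] - bc$outlet_pressure * ar[f] / 3
  }
  # body force contribution
  if (any(blood$body_force != 0)) {
    Vn <- abs(tet_volumes(lumen$nodes, lumen$elems))
    nodew <- numeric(nn)
    for (i in 1:4) {
      acc <- tapply(Vn / 4, lumen$elems[, i], sum)
      nodew[as.integer(names(acc))] <- nodew[as.integer(names(acc))] + acc
    }
    for (k in 1:3)
      b0[vel_dof(seq_len(nn), k)] <- b0[vel_dof(seq_len(nn), k)] +
        blood$density * blood$body_force[k] * nodew
  }

  elems <- matrix(as.integer(lumen$elems), ncol = 4)
  u <- matrix(0, nn, 3)
  picard <- 0L
  hist <- numeric(0)
  conv_on <- FALSE     # first pass: Stokes
  omega <- control$relax
  r_prev <- NULL
  repeat {
    sys <- flow_system(lumen$nodes, elems, u, blood$dynamic_viscosity,
                       blood$density, conv_on)
    K <- Matrix::sparseMatrix(i = sys$ti, j = sys$tj, x = sys$tx,
                              dims = c(4L * nn, 4L * nn))
    rhs <- b0[freed] - as.numeric(K[freed, fixed_dofs] %*% xfix[fixed_dofs])
    x <- Matrix::solve(K[freed, freed], rhs)
    xf <- xfix; xf[freed] <- as.numeric(x)
    unew <- matrix(xf[seq_len(3L * nn)], nn, 3, byrow = TRUE)
    pnew <- xf[3L * nn + seq_len(nn)]
    if (!conv_on && control$convection) {
      u <- unew; p <- pnew
      conv_on <- TRUE
      next     # Stokes initialization done; start Picard
    }
    resid <- unew - u
    du <- sqrt(sum(resid^2)) / max(sqrt(sum(unew^2)), 1e-300)
    hist <- c(hist, du)
    if (control$convection) {
      # Aitken delta-squared relaxation kills the limit cycles plain
      # under-relaxation falls into near the upper laminar range
      if (!is.null(r_prev)) {
        dr <- resid - r_prev
        dn <- sum(dr^2)
        if (dn > 0) omega <- max(0.05, min(1.5, -omega * sum(r_prev * dr) / dn))
      }
      r_prev <- resid
      u <- u + omega * resid
    } else u <- unew
    p <- pnew
    picard <- picard + 1L
    if (!control$convection) break
    if (du < control$tol) break
    if (picard >= control$max_iter) {
      err <- simpleError(sprintf(
        "Picard iteration did not converge (last change %.3e)", du))
      err$residual_history <- hist
      stop(err)
    }
  }

  sol <- structure(list(velocity = u, pressure = p, mesh = lumen,
                        converged = TRUE, picard_iterations = picard,
                        change_history = hist),
                   class = "flow_solution")
  sol$mass_balance <- mass_balance(sol)
  sol$mean_outlet_speed <- 100 * cross_section_speed(sol, frac = 1)$mean_speed
  sol$mean_mid_speed <- 100 * cross_section_speed(sol, frac = 0.5)$mean_speed
  sol$centerline_profile <- centerline_profile(sol)
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Steady flow solution: %d nodes, %d Picard iterations\n",
              nrow(x$velocity), x$picard_iterations))
  cat(sprintf("  mid-plane mean speed %.2f cm/s, outlet %.2f cm/s, mass defect %.2e\n",
              x$mean_mid_speed, x$mean_outlet_speed, x$mass_balance$defect))
  invisible(x)
}

# Flux, area and mean normal speed through the node layer closest to
# fraction `frac` of the lumen length (layers survive morphing).
cross_section_speed <- function(flow, frac = 0.5) {
  mesh <- flow$mesh
  np <- mesh$info$points_per_level
  nlev <- length(mesh$info$x_levels)
  lev <- 1L + round(frac * (nlev - 1L))
  idx <- (lev - 1L) * np + seq_len(np)
  tris <- mesh$info$disk_tris
  a <- mesh$nodes[idx[tris[, 1]], , drop = FALSE]
  b <- mesh$nodes[idx[tris[, 2]], , drop = FALSE]
  c3 <- mesh$nodes[idx[tris[, 3]], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (c3[, 3] - a[, 3]) -
               (b[, 3] - a[, 3]) * (c3[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c3[, 1] - a[, 1]) -
               (b[, 1] - a[, 1]) * (c3[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
               (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1])) / 2
  uavg <- (flow$velocity[idx[tris[, 1]], , drop = FALSE] +
           flow$velocity[idx[tris[, 2]], , drop = FALSE] +
           flow$velocity[idx[tris[, 3]], , drop = FALSE]) / 3
  flux <- sum(rowSums(uavg * nrm))
  # projected (vector-sum) area: equals the plane area for a planar section
  # and is unbiased by morphing-induced warp of the triangulated surface
  area <- sqrt(sum(colSums(nrm)^2))
  list(flux = flux, area = area, mean_speed = flux / area, level = lev)
}

# Discrete mass balance: inlet vs outlet vs mid-plane volumetric flux.
mass_balance <- function(flow) {
  qi <- cross_section_speed(flow, 0)$flux
  qm <- cross_section_speed(flow, 0.5)$flux
  qo <- cross_section_speed(flow, 1)$flux
  list(inlet = qi, mid = qm, outlet = qo,
       defect = max(abs(qo - qi), abs(qm - qi)) / abs(qi))
}

# Speed-vs-radius samples on the mid-lumen plane.
centerline_profile <- function(flow, frac = 0.5) {
  mesh <- flow$mesh
  np <- mesh$info$points_per_level
  nlev <- length(mesh$info$x_levels)
  lev <- 1L + round(frac * (nlev - 1L))
  idx <- (lev - 1L) * np + seq_len(np)
  r <- lumen_node_radius(mesh)[idx]
  sp <- sqrt(rowSums(flow$velocity[idx, , drop = FALSE]^2))
  out <- data.frame(r_mm = r * 1000, speed_cm_s = sp * 100)
  out[order(out$r_mm), ]
}

#' Write a centreline profile as CSV
#'
#' @param flow A `flow_solution`.
#' @param file Output path (columns `r_mm,speed_cm_s`).
#' @export
write_profile_csv <- function(flow, file) {
  utils::write.csv(flow$centerline_profile, file, row.names = FALSE)
}
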