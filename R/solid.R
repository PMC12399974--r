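# Static finite-strain solid mechanics of the tissue-artery system.

solid_material_arrays <- function(mesh, tissue, artery) {
  ne <- nrow(mesh$elems)
  c1 <- numeric(ne); kap <- numeric(ne); kloc <- numeric(ne)
  nodal <- logical(ne)
  is_t <- mesh$region == "tissue"
  is_w <- mesh$region == "artery_wall"
  if (any(!(is_t | is_w))) stop("solid mesh contains non-solid regions")
  # tissue: nodal-averaged-J mixed treatment carries the bulk stiffness;
  # a small local penalty (1% of K) in parallel suppresses spurious
  # nodal-pressure modes without re-introducing volumetric locking
  kloc_t <- 0.01 * tissue$bulk_modulus
  c1[is_t] <- tissue$C1
  kap[is_t] <- tissue$bulk_modulus - kloc_t
  kloc[is_t] <- kloc_t
  nodal[is_t] <- TRUE
  c1[is_w] <- artery$shear_modulus / 2
  kap[is_w] <- artery$bulk_modulus
  kloc[is_w] <- 0
  nodal[is_w] <- FALSE
  list(c1 = c1, kappa = kap, kloc = kloc, nodal = nodal)
}

# Nodes lying on facets with any of the given tags.
nodes_of_tags <- function(mesh, tags) {
  sel <- mesh$boundary_tag %in% tags
  sort(unique(as.vector(mesh$boundary_faces[sel, , drop = FALSE])))
}

# Consistent nodal force vector for a uniform traction over tagged facets.
traction_force_vector <- function(mesh, load) {
  sel <- mesh$boundary_tag == load$patch_tag
  if (!any(sel)) stop("load patch tag '", load$patch_tag, "' not present")
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  areas <- face_areas(mesh$nodes, faces)
  A <- sum(areas)
  if (A <= 0) stop("load patch area is zero")
  t_vec <- load$force_magnitude * load$direction / A
  f <- matrix(0, nrow(mesh$nodes), 3)
  idx <- as.vector(faces)
  w <- rep(areas / 3, 3)
  acc <- tapply(w, idx, sum)
  nodes <- as.integer(names(acc))
  for (k in 1:3) f[nodes, k] <- as.numeric(acc) * t_vec[k]
  attr(f, "patch_area") <- A
  f
}

#' Solver controls for the static solid problem
#'
#' @param tol Relative residual tolerance of the Newton iteration.
#' @param max_iter Maximum Newton iterations per load step.
#' @param step_force Load increment, N (10 increments at the 2 N study load).
#' @param max_line_search Backtracking halvings per iteration.
#' @export
solid_control <- function(tol = 1e-6, max_iter = 50, step_force = 0.2,
                          max_line_search = 12, verbose = FALSE) {
  list(tol = tol, max_iter = max_iter, step_force = step_force,
       max_line_search = max_line_search, verbose = verbose)
}

#' Solve the static traction problem
#'
#' Incremental-load Newton solution of the finite-strain equilibrium of the
#' tissue (Neo-Hookean, nodal-pressure anti-locking) and artery wall
#' (stiff, moduli from the linear-elastic parameters) under a dead traction
#' on the patch, with the tagged end faces fixed.
#'
#' @param mesh An `fsi_mesh`; a combined tissue-artery mesh is reduced to its
#'   solid part automatically.
#' @param tissue A [neo_hookean_material()].
#' @param artery A [linear_elastic_material()].
#' @param load A [traction_load()].
#' @param fixed_tags Boundary tags whose nodes are fully fixed.
#' @param fixed_components Optional named list `tag -> integer components`
#'   for roller-type supports (used in verification problems).
#' @param extra_constraints Optional list of `list(nodes=, comps=)` giving
#'   additional zero-displacement constraints on explicit node sets.
#' @param extra_nodal_forces Optional n x 3 matrix of additional nodal forces
#'   (N) in solid-mesh numbering (used for the fluid-pressure load in
#'   two-way coupling); ramped with the load factor.
#' @param control See [solid_control()].
#' @return A `solid_solution`: displacement (m, per node of the solid mesh),
#'   per-element `J` and von Mises stress (Pa), convergence metadata, and the
#'   solid mesh it lives on.
#' @export
solve_static <- function(mesh, tissue, artery = linear_elastic_material(),
                         load = traction_load(),
                         fixed_tags = c("fixed_end_A", "fixed_end_B"),
                         fixed_components = NULL,
                         extra_constraints = NULL,
                         extra_nodal_forces = NULL,
                         control = solid_control()) {
  stopifnot(inherits(mesh, "fsi_mesh"))
  sm <- if (any(mesh$region == "lumen")) solid_mesh(mesh) else mesh
  mats <- solid_material_arrays(sm, tissue, artery)
  nn <- nrow(sm$nodes)

  for (tg in c(fixed_tags, load$patch_tag, names(fixed_components)))
    if (!any(sm$boundary_tag == tg)) stop("boundary tag '", tg, "' not present")

  fixed <- matrix(FALSE, nn, 3)
  fixed[nodes_of_tags(sm, fixed_tags), ] <- TRUE
  for (tg in names(fixed_components))
    fixed[nodes_of_tags(sm, tg), fixed_components[[tg]]] <- TRUE
  for (cs in extra_constraints) fixed[cs$nodes, cs$comps] <- TRUE
  free <- which(!t(fixed))            # dof order: (node-1)*3 + comp

  f_ext <- traction_force_vector(sm, load)
  if (!is.null(extra_nodal_forces)) f_ext <- f_ext + extra_nodal_forces
  f_vec <- as.vector(t(f_ext))
  fnorm <- sqrt(sum(f_vec[free]^2))

  u <- matrix(0, nn, 3)
  pnod <- numeric(nn)
  n_steps <- if (load$force_magnitude == 0) 1L else
    max(1L, ceiling(load$force_magnitude / control$step_force))
  res_hist <- numeric(0)
  total_newton <- 0L
  elems <- matrix(as.integer(sm$elems), ncol = 4)

  assemble <- function(u, pnod, tangent)
    solid_system(sm$nodes, elems, u, pnod, mats$c1, mats$kappa,
                 mats$kloc, mats$nodal, tangent, FALSE)

  # dimensionless residual pair: force imbalance and pressure-law mismatch
  resid_of <- function(sys, lam, ref) {
    ru <- as.vector(t(sys$grad)) - lam * f_vec
    hasp <- sys$has_pressure > 0
    rp <- if (any(hasp)) max(abs(sys$rp[hasp] / sys$has_pressure[hasp])) else 0
    list(ru = ru, rn = sqrt(sum(ru[free]^2)), rp = rp,
         merit = sqrt(sum(ru[free]^2)) / ref + rp)
  }

  pdofs <- NULL
  slot_map <- NULL    # triplet -> CSC slot aggregation (pattern is fixed)
  Kskel <- NULL
  chol_sym <- NULL    # cached CHOLMOD symbolic analysis

  # one Newton solve at fixed load fraction lam, from the given state;
  # returns the new state or ok = FALSE (caller shrinks the increment)
  newton_at <- function(lam, u, pnod) {
    ref <- max(lam * fnorm, 1e-12)
    for (it in seq_len(control$max_iter)) {
      sys <- assemble(u, pnod, TRUE)
      if (isTRUE(sys$inverted)) return(list(ok = FALSE))
      if (is.null(pdofs)) pdofs <<- 3L * nn + which(sys$has_pressure > 0)
      rs <- resid_of(sys, lam, ref)
      res_hist <<- c(res_hist, rs$rn)
      if (rs$rn <= control$tol * ref && rs$rp <= max(control$tol, 1e-9))
        return(list(ok = TRUE, u = u, pnod = pnod, its = it - 1L))
      if (is.null(slot_map)) {
        Kskel <<- Matrix::sparseMatrix(i = sys$ti, j = sys$tj, x = sys$tx,
                                       dims = c(4 * nn, 4 * nn))
        o <- order(sys$tj, sys$ti)
        js <- sys$tj[o]; is_ <- sys$ti[o]
        ngrp <- c(TRUE, js[-1] != js[-length(js)] | is_[-1] != is_[-length(is_)])
        slot_map <<- list(o = o, grp = cumsum(ngrp))
        stopifnot(max(slot_map$grp) == length(Kskel@x))
        K <- Kskel
      } else {
        K <- Kskel
        K@x <- as.numeric(rowsum(sys$tx[slot_map$o], slot_map$grp,
                                 reorder = FALSE))
      }
      # exact static condensation of the (diagonal) pressure block:
      # [A B; B' -C] -> solve (A + B C^{-1} B') du = -ru - B C^{-1} rp,
      # then dp = C^{-1} (B' du + rp); the condensed matrix is symmetric
      # positive definite near equilibrium and CHOLMOD-friendly.
      pnodes <- pdofs - 3L * nn
      A <- K[free, free]
      B <- K[free, pdofs]
      Cvec <- as.numeric(sys$has_pressure)[pnodes] /
        as.numeric(sys$kbar)[pnodes]
      rp <- as.numeric(sys$rp)[pnodes]
      M <- Matrix::forceSymmetric(
        A + B %*% Matrix::Diagonal(x = 1 / Cvec) %*% Matrix::t(B))
      rhs <- -(rs$ru[free] + as.numeric(B %*% (rp / Cvec)))
      # CHOLMOD with Levenberg-style diagonal shift when the tangent is
      # indefinite away from equilibrium (never CSparse LU: its pivoting
      # fill on these systems is pathological)
      dscale <- mean(abs(Matrix::diag(M)))
      beta <- 0; sol <- NULL
      repeat {
        Mt <- if (beta > 0)
          M + Matrix::Diagonal(n = nrow(M), x = beta * dscale) else M
        ch <- suppressWarnings(try({
          if (is.null(chol_sym))
            Matrix::Cholesky(Mt, LDL = FALSE, super = TRUE, perm = TRUE)
          else stats::update(chol_sym, Mt)
        }, silent = TRUE))
        if (!inherits(ch, "try-error")) {
          chol_sym <<- ch
          sol <- Matrix::solve(ch, rhs)
          break
        }
        chol_sym <<- NULL
        beta <- if (beta == 0) 1e-8 else beta * 100
        if (beta > 10) break
      }
      if (is.null(sol)) return(list(ok = FALSE))
      du <- numeric(3 * nn); du[free] <- as.numeric(sol)
      dU <- matrix(du, nn, 3, byrow = TRUE)
      dP <- numeric(nn)
      dP[pnodes] <- (as.numeric(Matrix::t(B) %*% du[free]) + rp) / Cvec
      alpha <- 1; ok <- FALSE
      for (ls in seq_len(control$max_line_search)) {
        trial <- assemble(u + alpha * dU, pnod + alpha * dP, FALSE)
        if (!isTRUE(trial$inverted)) {
          mt <- resid_of(trial, lam, ref)$merit
          if (mt <= (1 - 1e-4 * alpha) * rs$merit) { ok <- TRUE; break }
        }
        alpha <- alpha / 2
      }
      if (!ok) return(list(ok = FALSE))   # no descent: shrink the increment
      u <- u + alpha * dU
      pnod <- pnod + alpha * dP
      total_newton <<- total_newton + 1L
      if (isTRUE(control$verbose))
        message(sprintf("  lam %.4f it %d: |r|=%.3e p-res=%.2e alpha=%g",
                        lam, it, rs$rn, rs$rp, alpha))
    }
    list(ok = FALSE)
  }

  # adaptive incremental loading with linear extrapolation predictor
  dlam0 <- if (load$force_magnitude == 0) 1 else 1 / n_steps
  lam <- 0; dlam <- dlam0
  du_s <- NULL; dp_s <- NULL; dlam_prev <- NA_real_
  while (lam < 1 - 1e-12) {
    dlam <- min(dlam, 1 - lam)
    u_try <- u; p_try <- pnod
    if (!is.null(du_s) && is.finite(dlam_prev) && dlam_prev > 0) {
      sc <- dlam / dlam_prev
      pred <- assemble(u + sc * du_s, pnod + sc * dp_s, FALSE)
      if (!isTRUE(pred$inverted)) {
        u_try <- u + sc * du_s; p_try <- pnod + sc * dp_s
      }
    }
    res <- newton_at(lam + dlam, u_try, p_try)
    if (res$ok) {
      du_s <- res$u - u; dp_s <- res$pnod - pnod
      u <- res$u; pnod <- res$pnod
      dlam_prev <- dlam
      lam <- lam + dlam
      if (res$its <= 4) dlam <- min(dlam * 1.5, dlam0)
    } else {
      dlam <- dlam / 2
      if (dlam < dlam0 / 64) {
        err <- simpleError(sprintf(
          "Newton failed to converge at load fraction %.3f (increment %.2e)",
          lam, dlam))
        err$residual_history <- res_hist
        stop(err)
      }
    }
  }

  fin <- solid_system(sm$nodes, elems, u, pnod, mats$c1, mats$kappa,
                      mats$kloc, mats$nodal, FALSE, TRUE)
  structure(list(displacement = u, J = as.numeric(fin$J),
                 Jbar = as.numeric(fin$Jbar),
                 von_mises_stress = as.numeric(fin$von_mises),
                 pressure = as.numeric(fin$pressure),
                 nodal_pressure = pnod,
                 converged = TRUE, newton_iterations = total_newton,
                 residual_history = res_hist, load = load,
                 mesh = sm),
            class = "solid_solution")
}

#' @export
print.solid_solution <- function(x, ...) {
  cat(sprintf("Static solid solution: %d nodes, %s, %d Newton iterations\n",
              nrow(x$displacement),
              if (x$converged) "converged" else "NOT converged",
              x$newton_iterations))
  cat(sprintf("  max |u| = %.3f cm, max von Mises = %.0f Pa, J in [%.3f, %.3f]\n",
              max(sqrt(rowSums(x$displacement^2))) * 100,
              max(x$von_mises_stress), min(x$J), max(x$J)))
  invisible(x)
}

#' Patch-average tissue deformation
#'
#' The study's deformation metric: mean displacement magnitude over the
#' traction-patch nodes (the grasped-tissue excursion), in cm. The maximum
#' displacement over tissue nodes is attached as attribute `max_tissue_cm`.
#'
#' @param solution A converged [solve_static()] result.
#' @param mesh Optional mesh; defaults to the solution's solid mesh.
#' @return Deformation in cm.
#' @export
tissue_deformation_metric <- function(solution, mesh = solution$mesh) {
  stopifnot(inherits(solution, "solid_solution"))
  if (!isTRUE(solution$converged)) stop("solution did not converge")
  sm <- if (any(mesh$region == "lumen")) solid_mesh(mesh) else mesh
  pn <- nodes_of_tags(sm, solution$load$patch_tag)
  mag <- sqrt(rowSums(solution$displacement^2))
  tis_nodes <- unique(as.vector(sm$elems[sm$region == "tissue", ]))
  structure(mean(mag[pn]) * 100,
            max_tissue_cm = max(mag[tis_nodes]) * 100)
}

#' Mean artery-wall von Mises stress
#'
#' Volume-weighted mean of the von Mises stress over `artery_wall` elements,
#' in Pa; the peak element value is attached as attribute `peak_Pa`.
#'
#' @param solution A converged [solve_static()] result.
#' @param mesh Optional mesh; defaults to the solution's solid mesh.
#' @return Mean wall stress, Pa.
#' @export
artery_wall_stress <- function(solution, mesh = solution$mesh) {
  stopifnot(inherits(solution, "solid_solution"))
  if (!isTRUE(solution$converged)) stop("solution did not converge")
  sm <- if (any(mesh$region == "lumen")) solid_mesh(mesh) else mesh
  wall <- sm$region == "artery_wall"
  if (!any(wall)) stop("mesh has no artery_wall region")
  V <- abs(tet_volumes(sm$nodes, sm$elems))[wall]
  vmw <- solution$von_mises_stress[wall]
  structure(sum(V * vmw) / sum(V), peak_Pa = max(vmw))
}

#' Force-thickness sweep of deformation and wall stress
#'
#' Runs [solve_static()] over a grid of geometries and traction forces and
#' tabulates the study metrics. Failed cells are flagged and the sweep
#' continues.
#'
#' @param params_list List of [geometry_params()] (one per thickness).
#' @param forces Traction forces, N.
#' @param tissue,artery Materials.
#' @param file Optional CSV path (`thickness_mm,force_N,deformation_cm,wall_stress_Pa`).
#' @param control See [solid_control()].
#' @return Data frame with one row per (thickness, force).
#' @export
force_sweep <- function(params_list, forces,
                        tissue = neo_hookean_material(),
                        artery = linear_elastic_material(),
                        file = NULL, control = solid_control()) {
  if (!length(params_list) || !length(forces)) stop("empty sweep grid")
  if (inherits(params_list, "geometry_params")) params_list <- list(params_list)
  rows <- list()
  for (p in params_list) {
    mesh <- build_tissue_artery_geometry(p)
    sm <- solid_mesh(mesh)
    for (f in forces) {
      res <- tryCatch({
        sol <- solve_static(sm, tissue, artery,
                            traction_load(force_magnitude = f),
                            control = control)
        data.frame(thickness_mm = p$tissue_thickness, force_N = f,
                   deformation_cm = as.numeric(tissue_deformation_metric(sol)),
                   wall_stress_Pa = as.numeric(artery_wall_stress(sol)),
                   converged = TRUE, error = NA_character_)
      }, error = function(e)
        data.frame(thickness_mm = p$tissue_thickness, force_N = f,
                   deformation_cm = NA_real_, wall_stress_Pa = NA_real_,
                   converged = FALSE, error = conditionMessage(e)))
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.csv(out[, c("thickness_mm", "force_N", "deformation_cm",
                             "wall_stress_Pa")], file, row.names = FALSE)
  out
}
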