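# Parametric tissue-artery geometry and tagged tetrahedral meshing.
#
# Internally every mesh is stored in SI units (metres); user-facing geometry
# parameters are millimetres, matching how the anatomy is reported.

#' Geometry parameters for the parametric tissue-artery model
#'
#' Describes a soft-tissue slab with an embedded straight innominate-artery
#' segment running along the x axis. `tissue_thickness` is the minimum
#' distance from the loaded (top) slab surface to the artery outer wall; the
#' slab height is `tissue_thickness + artery_outer_diameter + bottom_margin`.
#'
#' @param tissue_thickness Cover thickness above the artery outer wall, mm.
#'   The study strata use 5, 10 and 20 mm.
#' @param slab_length Slab extent along the artery axis, mm.
#' @param slab_width Slab extent across the artery, mm.
#' @param artery_outer_diameter Outer diameter of the artery, mm.
#' @param artery_wall_thickness Wall thickness, mm (lumen diameter =
#'   `artery_outer_diameter - 2 * artery_wall_thickness`).
#' @param lumen_length Length of the meshed lumen, mm (defaults to the slab
#'   length so the vessel spans the slab).
#' @param traction_patch_width,traction_patch_length Footprint of the
#'   instrument traction patch on the top face, mm.
#' @param traction_patch_offset Lateral (y) offset of the patch centre from
#'   the artery axis, mm. The default places the grasp just lateral to the
#'   projected artery edge: the instrument pulls the node-bearing soft tissue
#'   beside the vessel, never the vessel itself.
#' @param target_element_size Requested element size, mm.
#' @param bottom_margin Tissue below the artery, mm.
#' @param support_collar Radial margin of the perivascular tissue bed that
#'   embeds the artery below the mobile tissue plate, mm. The slab above the
#'   dissection plane has height `tissue_thickness`; beneath that plane only
#'   the collar of tissue around the artery remains, so the mobile layer
#'   responds with plate/membrane mechanics (thicker = stiffer) while stress
#'   still transmits to the artery wall.
#' @param areolar_gap Height of the loose-tissue layer between the plate
#'   underside and the artery outer wall, mm (floored at one element size).
#' @param dissection_window Axial length of the central segment over which
#'   the tissue has been dissected free of the vessel, mm: inside the window
#'   the plate is separated from the artery (the surgical working plane);
#'   outside it the perivascular attachments are intact and transmit stress
#'   to the wall.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(tissue_thickness = 5,
                            slab_length = 60,
                            slab_width = 40,
                            artery_outer_diameter = 12,
                            artery_wall_thickness = 1,
                            lumen_length = slab_length,
                            traction_patch_width = 12,
                            traction_patch_length = 12,
                            traction_patch_offset =
                              artery_outer_diameter / 2 + traction_patch_width / 2,
                            target_element_size = 1,
                            bottom_margin = 3,
                            support_collar = 3,
                            areolar_gap = max(1.5, target_element_size),
                            dissection_window = 20) {
  p <- list(tissue_thickness = tissue_thickness,
            slab_length = slab_length,
            slab_width = slab_width,
            artery_outer_diameter = artery_outer_diameter,
            artery_wall_thickness = artery_wall_thickness,
            lumen_length = lumen_length,
            traction_patch_width = traction_patch_width,
            traction_patch_length = traction_patch_length,
            traction_patch_offset = traction_patch_offset,
            target_element_size = target_element_size,
            bottom_margin = bottom_margin,
            support_collar = support_collar,
            areolar_gap = areolar_gap,
            dissection_window = dissection_window)
  lens <- unlist(p[setdiff(names(p),
                           c("traction_patch_offset", "dissection_window"))])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("geometry error: all geometry lengths must be finite and > 0")
  if (!is.finite(dissection_window) || dissection_window < 0 ||
      dissection_window > slab_length)
    stop("geometry error: dissection_window must be in [0, slab_length]")
  if (!is.finite(traction_patch_offset))
    stop("geometry error: traction_patch_offset must be finite")
  if (abs(traction_patch_offset) + traction_patch_width / 2 > slab_width / 2)
    stop("geometry error: traction patch does not fit inside the slab top face")
  if (artery_wall_thickness >= artery_outer_diameter / 2)
    stop("geometry error: artery_wall_thickness must be < artery_outer_diameter/2")
  if (traction_patch_length > slab_length || traction_patch_width > slab_width)
    stop("geometry error: traction patch does not fit inside the slab top face")
  if (lumen_length > slab_length)
    stop("geometry error: lumen_length exceeds slab_length")
  structure(p, class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Tissue-artery geometry parameters (mm):\n")
  cat(sprintf("  tissue cover %g, slab %g x %g, artery OD %g (wall %g), element size %g\n",
              x$tissue_thickness, x$slab_length, x$slab_width,
              x$artery_outer_diameter, x$artery_wall_thickness,
              x$target_element_size))
  invisible(x)
}

MM <- 1e-3  # mm -> m

new_fsi_mesh <- function(nodes, elems, region, boundary_faces, boundary_tag,
                         h, info = list()) {
  structure(list(nodes = nodes, elems = elems, region = region,
                 boundary_faces = boundary_faces, boundary_tag = boundary_tag,
                 h = h, info = info),
            class = "fsi_mesh")
}

#' @export
print.fsi_mesh <- function(x, ...) {
  cat(sprintf("Tagged tetrahedral mesh: %d nodes, %d elements\n",
              nrow(x$nodes), nrow(x$elems)))
  print(table(x$region))
  cat("boundary facets:\n")
  print(table(x$boundary_tag))
  invisible(x)
}

tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c3 <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
   b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
   b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
}

# Swap two nodes of negatively oriented tets so all volumes are positive.
orient_tets <- function(nodes, elems) {
  v <- tet_volumes(nodes, elems)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- elems[neg, 3]
    elems[neg, 3] <- elems[neg, 4]
    elems[neg, 4] <- tmp
  }
  elems
}

# All faces (as sorted node triples) with their parent element index.
tet_faces <- function(elems) {
  m <- nrow(elems)
  f <- rbind(elems[, c(1, 2, 3)], elems[, c(1, 2, 4)],
             elems[, c(1, 3, 4)], elems[, c(2, 3, 4)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  list(faces = f, sorted = cbind(lo, mid, hi), elem = rep(seq_len(m), 4))
}

# Multiplicity of each face among all tet faces (interior faces appear twice).
face_multiplicity <- function(sorted) {
  o <- order(sorted[, 1], sorted[, 2], sorted[, 3])
  s <- sorted[o, , drop = FALSE]
  n <- nrow(s)
  same_prev <- c(FALSE, rowSums(abs(s[-1, , drop = FALSE] -
                                    s[-n, , drop = FALSE])) == 0)
  grp <- cumsum(!same_prev)
  cnt <- tabulate(grp)
  mult <- integer(n); mult[o] <- cnt[grp]
  mult
}

# Boundary faces = faces owned by exactly one tet. Returns the face node
# triples (sorted; orientation is irrelevant downstream) and parent element.
boundary_faces_of <- function(elems) {
  tf <- tet_faces(elems)
  idx <- which(face_multiplicity(tf$sorted) == 1L)
  list(faces = tf$sorted[idx, , drop = FALSE], elem = tf$elem[idx])
}

# 6-tet split of the structured hex (i,j,k). Corner order:
# v0=(0,0,0) v1=(1,0,0) v2=(1,1,0) v3=(0,1,0) v4=(0,0,1) v5=(1,0,1)
# v6=(1,1,1) v7=(0,1,1); all tets share the main diagonal v0-v6, which makes
# the split conforming across a translated structured grid.
HEX6 <- matrix(c(0, 1, 2, 6,
                 0, 2, 3, 6,
                 0, 3, 7, 6,
                 0, 7, 4, 6,
                 0, 4, 5, 6,
                 0, 5, 1, 6) + 1L, ncol = 4, byrow = TRUE)

# Structured box grid split into tets. Dimensions in metres.
box_tet_grid <- function(lx, ly, lz, h) {
  nx <- max(1L, round(lx / h)); ny <- max(1L, round(ly / h))
  nz <- max(1L, round(lz / h))
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L + (ny + 1L) * (k - 1L))
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  i <- cells$i; j <- cells$j; k <- cells$k
  corner <- cbind(nid(i,     j,     k),     nid(i + 1, j,     k),
                  nid(i + 1, j + 1, k),     nid(i,     j + 1, k),
                  nid(i,     j,     k + 1), nid(i + 1, j,     k + 1),
                  nid(i + 1, j + 1, k + 1), nid(i,     j + 1, k + 1))
  nc <- nrow(cells)
  elems <- matrix(0L, nc * 6L, 4L)
  for (t in 1:6)
    elems[seq.int(t, by = 6L, length.out = nc), ] <- corner[, HEX6[t, ]]
  cell_of <- integer(nc * 6L)
  for (t in 1:6) cell_of[seq.int(t, by = 6L, length.out = nc)] <- seq_len(nc)
  list(nodes = nodes, elems = elems, cell_of = cell_of, cells = cells,
       nx = nx, ny = ny, nz = nz, xs = xs, ys = ys, zs = zs)
}

#' Structured tetrahedral box mesh
#'
#' A rectangular block meshed with a conforming 6-tet-per-hex structured grid,
#' used for solver verification (patch tests, oracle comparisons). Faces at
#' x = 0 and x = lx are tagged `fixed_end_A` / `fixed_end_B`; an optional
#' patch on the top face is tagged `traction_patch`; everything else is
#' `free_surface`.
#'
#' @param lx,ly,lz Box dimensions, mm.
#' @param h Target element size, mm.
#' @param patch Optional `c(width, length)` (mm) of a centred top-face patch.
#' @param region Region label for all elements.
#' @return An `fsi_mesh`.
#' @export
build_box_mesh <- function(lx, ly, lz, h, patch = NULL, region = "tissue") {
  g <- box_tet_grid(lx * MM, ly * MM, lz * MM, h * MM)
  elems <- orient_tets(g$nodes, g$elems)
  bf <- boundary_faces_of(elems)
  cen <- (g$nodes[bf$faces[, 1], ] + g$nodes[bf$faces[, 2], ] +
          g$nodes[bf$faces[, 3], ]) / 3
  tol <- 1e-9
  tag <- rep("free_surface", nrow(bf$faces))
  tag[abs(cen[, 1]) < tol] <- "fixed_end_A"
  tag[abs(cen[, 1] - lx * MM) < tol] <- "fixed_end_B"
  if (!is.null(patch)) {
    on_top <- abs(cen[, 3] - lz * MM) < tol
    inx <- abs(cen[, 1] - lx * MM / 2) <= patch[2] * MM / 2
    iny <- abs(cen[, 2] - ly * MM / 2) <= patch[1] * MM / 2
    tag[on_top & inx & iny] <- "traction_patch"
  }
  new_fsi_mesh(g$nodes, elems, rep(region, nrow(elems)), bf$faces, tag,
               h * MM, info = list(kind = "box", lx = lx, ly = ly, lz = lz))
}

# --- prism splitting (min-global-index face diagonals) ---------------------

# Split a triangular prism (bottom b1 b2 b3, top t1 t2 t3, ti above bi) into
# three tets whose quad-face diagonals each pass through the face's
# minimum-index vertex; the min-index rule can never produce the cyclic
# (untetrahedralizable) diagonal pattern, so neighbouring prisms agree.
prism_to_tets <- function(bot, top) {
  v <- c(bot, top)
  if (which.min(v) > 3L) {          # min vertex on top: flip the prism
    tmp <- bot; bot <- c(top[1], top[3], top[2]); top <- c(tmp[1], tmp[3], tmp[2])
    v <- c(bot, top)
  }
  r <- which.min(bot) - 1L          # rotate min-index bottom vertex to slot 1
  rot <- ((0:2 + r) %% 3L) + 1L
  b <- bot[rot]; t <- top[rot]
  # faces through b[1]: diagonals (b1,t2) and (b1,t3) are forced; remaining
  # quad face {b2,b3,t3,t2} picks its diagonal by the same min rule
  quad <- c(b[2], b[3], t[3], t[2])
  if (which.min(quad) %in% c(1L, 3L)) {   # diagonal (b2, t3)
    rbind(c(b[1], b[2], b[3], t[3]),
          c(b[1], b[2], t[3], t[2]),
          c(b[1], t[1], t[2], t[3]))
  } else {                                # diagonal (b3, t2)
    rbind(c(b[1], b[2], b[3], t[2]),
          c(b[1], b[3], t[3], t[2]),
          c(b[1], t[1], t[2], t[3]))
  }
}

# Triangulated disk (structured polar web): centre node + n_r rings of m
# points. Returns 2D points and triangles.
disk_triangulation <- function(radius, n_r, m) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  pts <- rbind(c(0, 0))
  for (i in seq_len(n_r)) {
    r <- radius * i / n_r
    pts <- rbind(pts, cbind(r * cos(th), r * sin(th)))
  }
  ring <- function(i, j) 1L + (i - 1L) * m + ((j - 1L) %% m) + 1L
  tris <- NULL
  tris <- matrix(0L, m + (n_r - 1L) * 2L * m, 3L)
  k <- 0L
  for (j in seq_len(m)) {                       # centre fan
    k <- k + 1L; tris[k, ] <- c(1L, ring(1, j), ring(1, j + 1))
  }
  if (n_r > 1) for (i in 1:(n_r - 1)) for (j in seq_len(m)) {
    a <- ring(i, j); b <- ring(i, j + 1); c3 <- ring(i + 1, j); d <- ring(i + 1, j + 1)
    k <- k + 1L; tris[k, ] <- c(a, b, d)
    k <- k + 1L; tris[k, ] <- c(a, d, c3)
  }
  tris <- tris[seq_len(k), , drop = FALSE]
  # consistent positive orientation (cross-section flux integration relies
  # on uniform normals after extrusion)
  sgn <- (pts[tris[, 2], 1] - pts[tris[, 1], 1]) *
         (pts[tris[, 3], 2] - pts[tris[, 1], 2]) -
         (pts[tris[, 2], 2] - pts[tris[, 1], 2]) *
         (pts[tris[, 3], 1] - pts[tris[, 1], 1])
  flip <- sgn < 0
  if (any(flip)) tris[flip, 2:3] <- tris[flip, 3:2]
  list(pts = pts, tris = tris)
}

#' Structured tetrahedral cylinder mesh
#'
#' A straight circular cylinder along the x axis, meshed by extruding a polar
#' disk triangulation into prisms and splitting each prism into three tets
#' with a min-vertex diagonal rule (conforming). Boundary tags: `inlet`
#' (x = 0), `outlet` (x = length), `fsi_wall` (lateral surface).
#'
#' @param radius Cylinder radius, mm.
#' @param length Cylinder length, mm.
#' @param h Target element size, mm.
#' @param centre `c(y, z)` position of the axis, mm.
#' @param region Region label (default "lumen").
#' @return An `fsi_mesh`; `info` records the axis geometry and axial levels.
#' @export
build_cylinder_mesh <- function(radius, length, h, centre = c(0, 0),
                                region = "lumen") {
  R <- radius * MM; L <- length * MM; hm <- h * MM
  n_r <- max(3L, round(R / hm))
  m <- 2L * max(4L, round(pi * R / hm))          # even: mirror-symmetric
  n_x <- max(2L, round(L / hm))
  disk <- disk_triangulation(R, n_r, m)
  np <- nrow(disk$pts)
  xs <- seq(0, L, length.out = n_x + 1)
  nodes <- cbind(rep(xs, each = np),
                 rep(disk$pts[, 1], n_x + 1) + centre[1] * MM,
                 rep(disk$pts[, 2], n_x + 1) + centre[2] * MM)
  nt <- nrow(disk$tris)
  elems <- matrix(0L, nt * n_x * 3L, 4L)
  k <- 0L
  for (s in seq_len(n_x)) {
    off_b <- (s - 1L) * np; off_t <- s * np
    for (t in seq_len(nt)) {
      tt <- prism_to_tets(disk$tris[t, ] + off_b, disk$tris[t, ] + off_t)
      elems[k + 1:3, ] <- tt
      k <- k + 3L
    }
  }
  elems <- orient_tets(nodes, elems)
  bf <- boundary_faces_of(elems)
  cen <- (nodes[bf$faces[, 1], ] + nodes[bf$faces[, 2], ] +
          nodes[bf$faces[, 3], ]) / 3
  tol <- 1e-9
  tag <- rep("fsi_wall", nrow(bf$faces))
  tag[abs(cen[, 1]) < tol] <- "inlet"
  tag[abs(cen[, 1] - L) < tol] <- "outlet"
  new_fsi_mesh(nodes, elems, rep(region, nrow(elems)), bf$faces, tag, hm,
               info = list(kind = "cylinder", radius = R, length = L,
                           centre = centre * MM, n_r = n_r, m = m,
                           x_levels = xs, points_per_level = np,
                           disk_tris = disk$tris))
}

# --- the full tissue-artery geometry ---------------------------------------

#' Build the parametric tissue-artery mesh
#'
#' Constructs the tagged tetrahedral mesh of the soft-tissue slab with the
#' embedded innominate-artery segment. The solid part (tissue + artery wall)
#' is a conforming structured grid in which wall elements are those
#' intersecting the annulus between lumen and outer radius; the lumen is a
#' separately meshed smooth cylinder (partitioned-FSI style) whose lateral
#' surface carries the `fsi_wall` tag, as does the facing solid surface.
#'
#' @param params A [geometry_params()] object.
#' @return An `fsi_mesh` with regions `tissue`, `artery_wall`, `lumen` and the
#'   seven boundary tags `fixed_end_A`, `fixed_end_B`, `traction_patch`,
#'   `inlet`, `outlet`, `fsi_wall`, `free_surface`.
#' @export
build_tissue_artery_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  p <- params
  h <- p$target_element_size * MM
  lx <- p$slab_length * MM; ly <- p$slab_width * MM
  R_o <- p$artery_outer_diameter * MM / 2
  R_l <- R_o - p$artery_wall_thickness * MM
  gap <- max(p$areolar_gap, p$target_element_size) * MM
  lz <- p$tissue_thickness * MM + gap +
    (p$artery_outer_diameter + p$bottom_margin) * MM
  ay <- ly / 2                                   # artery axis position
  plane_z <- lz - p$tissue_thickness * MM        # dissection plane
  az <- plane_z - gap - R_o
  if (az - R_o < 0) stop("geometry error: artery does not fit below the tissue cover")

  g <- box_tet_grid(lx, ly, lz, h)
  # classify hex cells by distance of their (y,z) cross-section to the axis
  cs <- g$cells
  y0 <- g$ys[cs$j]; y1 <- g$ys[cs$j + 1]; z0 <- g$zs[cs$k]; z1 <- g$zs[cs$k + 1]
  dy <- pmax(y0 - ay, ay - y1, 0); dz <- pmax(z0 - az, az - z1, 0)
  rmin <- sqrt(dy^2 + dz^2)
  ry <- pmax(abs(y0 - ay), abs(y1 - ay)); rz <- pmax(abs(z0 - az), abs(z1 - az))
  rmax <- sqrt(ry^2 + rz^2)
  hole <- rmax <= R_l + 1e-12                    # cells fully inside the lumen
  wall <- !hole & rmin < R_o - 1e-12 & rmax > R_l + 1e-12
  # void below the dissection plane: outside the perivascular collar
  # everywhere, and all non-vessel tissue inside the dissection window --
  # there the mobile plate is freed from the vessel (surgical working plane)
  xc <- (g$xs[cs$i] + g$xs[cs$i + 1]) / 2
  in_window <- abs(xc - lx / 2) < p$dissection_window * MM / 2
  void <- !hole & !wall & (z1 <= plane_z + 1e-12) &
    ((rmin >= R_o + p$support_collar * MM - 1e-12) | in_window)
  cell_region <- ifelse(hole | void, "hole",
                        ifelse(wall, "artery_wall", "tissue"))
  keep_elem <- cell_region[g$cell_of] != "hole"
  elems <- g$elems[keep_elem, , drop = FALSE]
  region <- cell_region[g$cell_of][keep_elem]
  # drop unused nodes, renumber
  used <- sort(unique(as.vector(elems)))
  renum <- integer(nrow(g$nodes)); renum[used] <- seq_along(used)
  elems <- matrix(renum[elems], ncol = 4)
  nodes <- g$nodes[used, , drop = FALSE]
  elems <- orient_tets(nodes, elems)
  if (!any(region == "artery_wall"))
    stop("meshing failure in region artery_wall: element size too coarse for the wall annulus")

  bf <- boundary_faces_of(elems)
  cen <- (nodes[bf$faces[, 1], ] + nodes[bf$faces[, 2], ] +
          nodes[bf$faces[, 3], ]) / 3
  tol <- 1e-9
  on_box <- (abs(cen[, 1]) < tol) | (abs(cen[, 1] - lx) < tol) |
            (abs(cen[, 2]) < tol) | (abs(cen[, 2] - ly) < tol) |
            (abs(cen[, 3]) < tol) | (abs(cen[, 3] - lz) < tol)
  tag <- rep("free_surface", nrow(bf$faces))
  # interior surfaces: the staircase lumen hole (near the axis) is the solid
  # side of the FSI interface; carved void surfaces are free
  rcen <- sqrt((cen[, 2] - ay)^2 + (cen[, 3] - az)^2)
  tag[!on_box & rcen < (R_l + R_o) / 2] <- "fsi_wall"
  tag[abs(cen[, 1]) < tol] <- "fixed_end_A"
  tag[abs(cen[, 1] - lx) < tol] <- "fixed_end_B"
  on_top <- abs(cen[, 3] - lz) < tol
  inx <- abs(cen[, 1] - lx / 2) <= p$traction_patch_length * MM / 2
  iny <- abs(cen[, 2] - (ay + p$traction_patch_offset * MM)) <=
    p$traction_patch_width * MM / 2
  tag[on_top & inx & iny] <- "traction_patch"
  if (!any(tag == "traction_patch"))
    stop("meshing failure in region traction_patch: patch smaller than one facet")

  lum <- build_cylinder_mesh(R_l / MM, p$lumen_length,
                             p$target_element_size,
                             centre = c(ay, az) / MM)
  # offset the lumen sub-mesh onto the slab coordinates and concatenate
  off <- nrow(nodes)
  lum_nodes <- lum$nodes
  lum_nodes[, 1] <- lum_nodes[, 1] + (lx - p$lumen_length * MM) / 2
  all_nodes <- rbind(nodes, lum_nodes)
  all_elems <- rbind(elems, lum$elems + off)
  all_region <- c(region, lum$region)
  all_bfaces <- rbind(bf$faces, lum$boundary_faces + off)
  all_tag <- c(tag, lum$boundary_tag)
  lum$info$node_offset <- off
  new_fsi_mesh(all_nodes, all_elems, all_region, all_bfaces, all_tag, h,
               info = list(kind = "tissue_artery", params = p,
                           lx = lx, ly = ly, lz = lz,
                           axis_y = ay, axis_z = az,
                           R_lumen = R_l, R_outer = R_o,
                           solid_n_nodes = off, lumen = lum$info))
}

#' Extract the lumen sub-mesh from a tissue-artery mesh
#'
#' @param mesh An `fsi_mesh` from [build_tissue_artery_geometry()].
#' @return An `fsi_mesh` containing only the lumen region with its own node
#'   numbering (tags `inlet`, `outlet`, `fsi_wall`).
#' @export
lumen_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "fsi_mesh"))
  if (identical(mesh$info$kind, "cylinder")) return(mesh)
  keep <- mesh$region == "lumen"
  if (!any(keep)) stop("mesh has no lumen region")
  elems <- mesh$elems[keep, , drop = FALSE]
  used <- sort(unique(as.vector(elems)))
  renum <- integer(nrow(mesh$nodes)); renum[used] <- seq_along(used)
  nodes <- mesh$nodes[used, , drop = FALSE]
  elems <- matrix(renum[elems], ncol = 4)
  bsel <- mesh$boundary_tag %in% c("inlet", "outlet") |
    (mesh$boundary_tag == "fsi_wall" &
       apply(matrix(mesh$boundary_faces %in% used, ncol = 3), 1, all) &
       mesh$boundary_faces[, 1] > mesh$info$solid_n_nodes)
  bfaces <- matrix(renum[mesh$boundary_faces[bsel, , drop = FALSE]], ncol = 3)
  info <- mesh$info$lumen
  info$centre <- c(mesh$info$axis_y, mesh$info$axis_z)
  info$x_levels <- info$x_levels +
    (mesh$info$lx - info$length) / 2
  new_fsi_mesh(nodes, elems, rep("lumen", nrow(elems)), bfaces,
               mesh$boundary_tag[bsel], mesh$h, info = info)
}

#' Extract the solid (tissue + artery wall) sub-mesh
#'
#' @param mesh An `fsi_mesh` from [build_tissue_artery_geometry()].
#' @return An `fsi_mesh` with regions `tissue`/`artery_wall`; `info$orig_node`
#'   maps back to the parent mesh numbering.
#' @export
solid_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "fsi_mesh"))
  keep <- mesh$region != "lumen"
  elems <- mesh$elems[keep, , drop = FALSE]
  used <- sort(unique(as.vector(elems)))
  renum <- integer(nrow(mesh$nodes)); renum[used] <- seq_along(used)
  nodes <- mesh$nodes[used, , drop = FALSE]
  new_elems <- matrix(renum[elems], ncol = 4)
  bsel <- apply(matrix(mesh$boundary_faces %in% used, ncol = 3), 1, all) &
    !(mesh$boundary_tag %in% c("inlet", "outlet"))
  if (!is.null(mesh$info$solid_n_nodes))
    bsel <- bsel & mesh$boundary_faces[, 1] <= mesh$info$solid_n_nodes
  bfaces <- matrix(renum[mesh$boundary_faces[bsel, , drop = FALSE]], ncol = 3)
  info <- mesh$info
  info$orig_node <- used
  new_fsi_mesh(nodes, new_elems, mesh$region[keep], bfaces,
               mesh$boundary_tag[bsel], mesh$h, info = info)
}

#' Mean radius-ratio mesh quality
#'
#' Per-element quality is `3 * r_in / r_circ` (inscribed over circumscribed
#' sphere radius, scaled so a regular tetrahedron scores 1); the mesh score is
#' the mean over elements.
#'
#' @param mesh An `fsi_mesh`.
#' @return Mean quality in \[0, 1\], with the per-element vector attached as
#'   attribute `per_element`.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "fsi_mesh"))
  if (nrow(mesh$elems) == 0) stop("empty mesh")
  q <- tet_radius_ratio(mesh$nodes, mesh$elems)
  structure(mean(q), per_element = q)
}

tet_radius_ratio <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]; b <- nodes[elems[, 2], , drop = FALSE]
  c3 <- nodes[elems[, 3], , drop = FALSE]; d <- nodes[elems[, 4], , drop = FALSE]
  V <- abs(tet_volumes(nodes, elems))
  tri_area <- function(p, q, r) {
    u <- q - p; v <- r - p
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  A <- tri_area(a, b, c3) + tri_area(a, b, d) + tri_area(a, c3, d) +
       tri_area(b, c3, d)
  r_in <- 3 * V / A
  # circumcentre from 2 (v_i - a) . x = |v_i|^2 - |a|^2, solved by Cramer
  m1 <- b - a; m2 <- c3 - a; m3 <- d - a
  r1 <- rowSums(b^2 - a^2) / 2; r2 <- rowSums(c3^2 - a^2) / 2
  r3 <- rowSums(d^2 - a^2) / 2
  det3 <- function(x, y, z)
    x[, 1] * (y[, 2] * z[, 3] - y[, 3] * z[, 2]) -
    x[, 2] * (y[, 1] * z[, 3] - y[, 3] * z[, 1]) +
    x[, 3] * (y[, 1] * z[, 2] - y[, 2] * z[, 1])
  D <- det3(m1, m2, m3)
  xc <- det3(cbind(r1, m1[, 2], m1[, 3]), cbind(r2, m2[, 2], m2[, 3]),
             cbind(r3, m3[, 2], m3[, 3])) / D
  yc <- det3(cbind(m1[, 1], r1, m1[, 3]), cbind(m2[, 1], r2, m2[, 3]),
             cbind(m3[, 1], r3, m3[, 3])) / D
  zc <- det3(cbind(m1[, 1], m1[, 2], r1), cbind(m2[, 1], m2[, 2], r2),
             cbind(m3[, 1], m3[, 2], r3)) / D
  R_c <- sqrt((xc - a[, 1])^2 + (yc - a[, 2])^2 + (zc - a[, 3])^2)
  pmin(1, pmax(0, 3 * r_in / R_c))
}

# Facet areas (m^2) for a set of boundary faces.
face_areas <- function(nodes, faces) {
  p <- nodes[faces[, 1], , drop = FALSE]
  q <- nodes[faces[, 2], , drop = FALSE]
  r <- nodes[faces[, 3], , drop = FALSE]
  u <- q - p; v <- r - p
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}
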