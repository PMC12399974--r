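# Mesh and field export/import: legacy VTK unstructured grid (ASCII) and
# Gmsh MSH 2.2. Coordinates are written in metres, as stored.

REGION_IDS <- c(tissue = 1L, artery_wall = 2L, lumen = 3L)

#' Write a mesh (with optional fields) as a legacy VTK unstructured grid
#'
#' @param mesh An `fsi_mesh`.
#' @param file Output path (`.vtk`).
#' @param point_data Named list of per-node vectors or n x 3 matrices.
#' @param cell_data Named list of per-element vectors.
#' @export
write_vtk_mesh <- function(mesh, file, point_data = NULL, cell_data = NULL) {
  stopifnot(inherits(mesh, "fsi_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tissue-artery mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(mesh$nodes, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(10L, ne)), con)

  cd <- c(list(region = unname(REGION_IDS[mesh$region])),
          if (is.null(cell_data)) list() else cell_data)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  for (nm in names(cd)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(as.numeric(cd[[nm]]), digits = 17, trim = TRUE), con)
  }
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v, digits = 17, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(v), digits = 17, trim = TRUE), con)
      }
    }
  }
  invisible(file)
}

#' Read a legacy VTK unstructured tetrahedral mesh
#'
#' Supports the subset written by [write_vtk_mesh()] (linear tets, region
#' cell scalars). Boundary faces are re-derived; tags are not preserved.
#'
#' @param file Path to a `.vtk` file.
#' @return An `fsi_mesh`.
#' @export
read_vtk_mesh <- function(file) {
  ln <- readLines(file)
  ip <- grep("^POINTS", ln)[1]
  nn <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = ln[(ip + 1):(ip + nn)], quiet = TRUE),
                  nn, 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cells <- matrix(scan(text = ln[(ic + 1):(ic + ne)], quiet = TRUE),
                  ne, 5, byrow = TRUE)
  if (any(cells[, 1] != 4)) stop("only linear tetrahedra are supported")
  elems <- matrix(as.integer(cells[, 2:5] + 1L), ncol = 4)
  region <- rep("tissue", ne)
  ir <- grep("^SCALARS region", ln)
  if (length(ir)) {
    vals <- as.integer(scan(text = ln[(ir[1] + 2):(ir[1] + 1 + ne)],
                            quiet = TRUE))
    region <- names(REGION_IDS)[vals]
  }
  bf <- boundary_faces_of(elems)
  hs <- unique(round(diff(sort(unique(nodes[, 1]))), 12))
  new_fsi_mesh(nodes, elems, region, bf$faces,
               rep("free_surface", nrow(bf$faces)),
               h = if (length(hs)) min(hs[hs > 0]) else NA_real_,
               info = list(kind = "imported"))
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Elements carry their region id as the physical tag; boundary faces are
#' written as triangles tagged by boundary-tag index.
#'
#' @param mesh An `fsi_mesh`.
#' @param file Output path (`.msh`).
#' @export
write_gmsh_mesh <- function(mesh, file) {
  stopifnot(inherits(mesh, "fsi_mesh"))
  con <- file(file, "w")
  on.exit(close(con))
  tags <- sort(unique(mesh$boundary_tag))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  utils::write.table(cbind(seq_len(nrow(mesh$nodes)),
                           format(mesh$nodes, digits = 17, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  nf <- nrow(mesh$boundary_faces); ne <- nrow(mesh$elems)
  writeLines(c("$EndNodes", "$Elements", as.character(nf + ne)), con)
  # triangles (type 2): physical tag = boundary tag index
  utils::write.table(cbind(seq_len(nf), 2L, 2L,
                           match(mesh$boundary_tag, tags),
                           match(mesh$boundary_tag, tags),
                           mesh$boundary_faces),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  # tets (type 4): physical tag = region id
  rid <- unname(REGION_IDS[mesh$region])
  utils::write.table(cbind(nf + seq_len(ne), 4L, 2L, rid, rid, mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndElements", "$BoundaryTagNames",
               paste(seq_along(tags), tags), "$EndBoundaryTagNames"), con)
  invisible(file)
}

#' Read a Gmsh MSH 2.2 tetrahedral mesh written by [write_gmsh_mesh()]
#'
#' @param file Path to a `.msh` file.
#' @return An `fsi_mesh` with regions and boundary tags restored.
#' @export
read_gmsh_mesh <- function(file) {
  ln <- readLines(file)
  i0 <- grep("^\\$Nodes$", ln)[1]
  nn <- as.integer(ln[i0 + 1])
  nd <- matrix(scan(text = ln[(i0 + 2):(i0 + 1 + nn)], quiet = TRUE),
               nn, 4, byrow = TRUE)
  nodes <- nd[order(nd[, 1]), 2:4, drop = FALSE]
  ie <- grep("^\\$Elements$", ln)[1]
  nel <- as.integer(ln[ie + 1])
  rows <- strsplit(ln[(ie + 2):(ie + 1 + nel)], "\\s+")
  tri <- list(); tet <- list()
  for (r in rows) {
    v <- as.integer(r)
    if (v[2] == 2L) tri[[length(tri) + 1]] <- v
    else if (v[2] == 4L) tet[[length(tet) + 1]] <- v
  }
  tetm <- do.call(rbind, tet)
  trim <- do.call(rbind, tri)
  elems <- tetm[, 6:9, drop = FALSE]
  region <- names(REGION_IDS)[tetm[, 4]]
  it <- grep("^\\$BoundaryTagNames$", ln)[1]
  tag_names <- character(0)
  if (!is.na(it)) {
    j <- it + 1
    while (!grepl("^\\$End", ln[j])) {
      parts <- strsplit(trimws(ln[j]), "\\s+")[[1]]
      tag_names[as.integer(parts[1])] <- parts[2]
      j <- j + 1
    }
  }
  btag <- if (length(tag_names)) tag_names[trim[, 4]] else
    rep("free_surface", nrow(trim))
  new_fsi_mesh(nodes, elems, region, trim[, 6:8, drop = FALSE], btag,
               h = NA_real_, info = list(kind = "imported"))
}

#' Export solution fields on the solid mesh
#'
#' Writes displacement, von Mises stress and the volume ratio J of a
#' [solve_static()] solution as a VTK unstructured grid.
#'
#' @param solution A `solid_solution`.
#' @param file Output path.
#' @export
write_solid_vtk <- function(solution, file) {
  write_vtk_mesh(solution$mesh, file,
                 point_data = list(displacement = solution$displacement),
                 cell_data = list(von_mises = solution$von_mises_stress,
                                  J = solution$J))
}

#' Export velocity/pressure fields of a flow solution
#'
#' @param flow A `flow_solution`.
#' @param file Output path.
#' @export
write_flow_vtk <- function(flow, file) {
  write_vtk_mesh(flow$mesh, file,
                 point_data = list(velocity = flow$velocity,
                                   pressure = flow$pressure))
}
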