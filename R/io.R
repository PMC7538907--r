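#' Write a hexahedral mesh (optionally with a solution) as legacy VTK
#'
#' Plain-text legacy VTK unstructured-grid output readable by ParaView.
#'
#' @param mesh a `hex_mesh`.
#' @param path output file.
#' @param point_data optional named list of per-node vectors (n x 3
#'   matrices) or scalars (length-n vectors).
#' @return `path`, invisibly.
#' @export
write_vtk_hex <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$conn)
  writeLines(c("# vtk DataFile Version 3.0",
               "eftfm hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9L), con)
  utils::write.table(cbind(8L, mesh$conn - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v, digits = 10, trim = TRUE),
                           con, row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(v), digits = 10, trim = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Write a forward solution (mesh + displacements) as legacy VTK
#'
#' @param solution a [solve_forward()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk_solution <- function(solution, path) {
  stopifnot(inherits(solution, "field_solution"))
  write_vtk_hex(solution$mesh, path,
                point_data = list(displacement = solution$u,
                                  magnitude = sqrt(rowSums(solution$u^2))))
}

#' Write a planar displacement grid as CSV
#'
#' One row per grid node: plane coordinates and the three displacement
#' components; this is also the boundary-condition exchange format.
#'
#' @param grid a `planar_displacement_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  nxn <- length(grid$x); nyn <- length(grid$y)
  df <- data.frame(node = seq_len(nxn * nyn),
                   x = rep(grid$x, times = nyn),
                   y = rep(grid$y, each = nxn),
                   ux = as.vector(grid$ux), uy = as.vector(grid$uy),
                   uz = as.vector(grid$uz))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a traction field as CSV
#'
#' @param tf a `traction_field` with geometry attached.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traction_csv <- function(tf, path) {
  stopifnot(inherits(tf, "traction_field"))
  df <- data.frame(x = tf$vertices[, 1], y = tf$vertices[, 2],
                   z = tf$vertices[, 3],
                   nx = tf$normals[, 1], ny = tf$normals[, 2],
                   nz = tf$normals[, 3],
                   tx = tf$traction[, 1], ty = tf$traction[, 2],
                   tz = tf$traction[, 3], magnitude = tf$magnitude)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
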