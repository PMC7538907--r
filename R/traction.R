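#' Project quadrature-point stresses to the deformed top surface
#'
#' Cauchy stresses live at the 2x2x2 quadrature points of each element;
#' for traction evaluation they are projected to the deformed top-surface
#' vertices by trilinear extrapolation within each top-layer element
#' followed by averaging of the contributions that meet at shared vertices.
#' The projection reproduces constant and linear stress fields exactly.
#'
#' @param solution a [solve_forward()] result.
#' @return List with `vertex_stress` (n x 6 Voigt: xx, yy, zz, xy, xz, yz),
#'   `vertices` (deformed positions, n x 3), `ref_vertices`, and the
#'   top-surface grid dimensions `dims`.
#' @export
project_stress_to_surface <- function(solution) {
  stopifnot(inherits(solution, "field_solution"))
  mesh <- solution$mesh
  nxn <- length(mesh$xs); nyn <- length(mesh$ys); nzn <- length(mesh$zs)
  ex <- nxn - 1L; ey <- nyn - 1L; ez <- nzn - 1L
  top_elems <- ((ez - 1L) * ex * ey + 1L):(ez * ex * ey)
  ## trilinear extrapolation matrix from the 8 qp to the 8 corners
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  qsgn <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1),
                                sz = c(-1, 1)))  # qp order: x fastest
  Mex <- matrix(0, 8, 8)
  for (a in 1:8) for (q in 1:8)
    Mex[a, q] <- prod((1 + sqrt(3) * sgn[a, ] * qsgn[q, ]) / 2)
  top_ids <- mesh$faces$top
  id_map <- integer(nrow(mesh$nodes)); id_map[top_ids] <- seq_along(top_ids)
  acc <- matrix(0, length(top_ids), 6)
  cnt <- numeric(length(top_ids))
  for (e in top_elems) {
    rows <- ((e - 1L) * 8L + 1L):(e * 8L)
    nodal <- Mex %*% solution$qp$sigma[rows, , drop = FALSE]
    corners <- mesh$conn[e, 5:8]             # top face of the element
    li <- id_map[corners]
    acc[li, ] <- acc[li, ] + nodal[5:8, ]
    cnt[li] <- cnt[li] + 1
  }
  vs <- acc / cnt
  verts <- solution$deformed[top_ids, , drop = FALSE]
  ## degenerate (folded) surface check: deformed cells must keep positive
  ## projected area
  xg <- matrix(verts[, 1], nxn, nyn); yg <- matrix(verts[, 2], nxn, nyn)
  if (any(diff(xg[, 1]) <= 0) || any(diff(yg[1, ]) <= 0))
    stop("degenerate (folded) deformed surface")
  if (any(!is.finite(verts))) stop("degenerate deformed surface")
  list(vertex_stress = vs, vertices = verts,
       ref_vertices = mesh$nodes[top_ids, , drop = FALSE],
       dims = c(nxn, nyn))
}

#' Triangulate the deformed top surface and compute outward unit normals
#'
#' The top-surface vertices (a structured grid in the reference plane) are
#' triangulated by splitting each quadrilateral cell along its shorter
#' deformed diagonal, which is the locally Delaunay choice; per-vertex
#' normals are the area-weighted average of incident triangle normals,
#' normalized and oriented outward (+z for this nominally upward surface).
#'
#' @param vertices deformed top-surface vertex positions (n x 3, um),
#'   ordered x-fastest on the structured `dims` grid.
#' @param dims grid dimensions `(nx, ny)` of the vertex layout.
#' @return List with `normals` (n x 3 unit vectors) and `triangles`
#'   (m x 3 vertex indices).
#' @export
surface_normals <- function(vertices, dims) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  nxn <- dims[1]; nyn <- dims[2]
  if (nrow(vertices) != nxn * nyn) stop("vertex count does not match dims")
  if (nrow(vertices) < 3L) stop("need at least 3 vertices")
  if (nxn < 2L || nyn < 2L)
    stop("collinear vertex set: a 2D vertex grid is required")
  vid <- function(i, j) i + (j - 1L) * nxn
  ci <- rep(seq_len(nxn - 1L), times = nyn - 1L)
  cj <- rep(seq_len(nyn - 1L), each = nxn - 1L)
  a <- vid(ci, cj); b <- vid(ci + 1L, cj)
  cc <- vid(ci + 1L, cj + 1L); d <- vid(ci, cj + 1L)
  d_ac <- rowSums((vertices[a, , drop = FALSE] - vertices[cc, , drop = FALSE])^2)
  d_bd <- rowSums((vertices[b, , drop = FALSE] - vertices[d, , drop = FALSE])^2)
  use_ac <- d_ac <= d_bd
  tri <- rbind(
    cbind(a, b, cc)[use_ac, , drop = FALSE],
    cbind(a, cc, d)[use_ac, , drop = FALSE],
    cbind(a, b, d)[!use_ac, , drop = FALSE],
    cbind(b, cc, d)[!use_ac, , drop = FALSE])
  v1 <- vertices[tri[, 2], , drop = FALSE] - vertices[tri[, 1], , drop = FALSE]
  v2 <- vertices[tri[, 3], , drop = FALSE] - vertices[tri[, 1], , drop = FALSE]
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 <= 0)) stop("collinear vertices: degenerate triangulation")
  flip <- cr[, 3] < 0                        # orient outward (+z)
  cr[flip, ] <- -cr[flip, ]
  ## accumulate area-weighted (cross-product) normals at vertices
  normals <- matrix(0, nrow(vertices), 3)
  for (v in 1:3) {
    for (c in 1:3) {
      s <- rowsum(cr[, c], tri[, v])
      normals[as.integer(rownames(s)), c] <-
        normals[as.integer(rownames(s)), c] + s[, 1]
    }
  }
  nn <- sqrt(rowSums(normals^2))
  if (any(nn == 0)) stop("isolated vertex in triangulation")
  normals <- normals / nn
  list(normals = normals, triangles = tri)
}

#' Cauchy traction vectors on the deformed top surface
#'
#' Applies the Cauchy relation `T(n) = n . sigma` at each surface vertex.
#' For the symmetric Cauchy stress the row/column convention is immaterial;
#' symmetry is asserted rather than assumed when a full tensor is given.
#'
#' @param vertex_stresses n x 6 Voigt matrix (xx, yy, zz, xy, xz, yz) or an
#'   n x 3 x 3 array of stress tensors (Pa).
#' @param normals n x 3 unit outward normals.
#' @param vertices optional deformed vertex positions to attach.
#' @param triangles optional triangulation to attach (enables
#'   [integrate_traction()]).
#' @param sym_tol relative symmetry tolerance for full-tensor input.
#' @return A `traction_field`: data-frame-free list with `vertices`,
#'   `normals`, `traction` (n x 3, Pa), `magnitude`, `in_plane`,
#'   `out_of_plane` and `triangles`.
#' @export
compute_traction <- function(vertex_stresses, normals, vertices = NULL,
                             triangles = NULL, sym_tol = 1e-6) {
  normals <- matrix(as.numeric(normals), ncol = 3)
  if (max(abs(sqrt(rowSums(normals^2)) - 1)) > 1e-6)
    stop("normals must be unit vectors")
  if (is.array(vertex_stresses) && length(dim(vertex_stresses)) == 3L) {
    S <- vertex_stresses
    asym <- max(abs(S - aperm(S, c(1, 3, 2))))
    if (asym > sym_tol * max(abs(S), 1e-300))
      stop("non-symmetric stress beyond tolerance")
    voigt <- cbind(S[, 1, 1], S[, 2, 2], S[, 3, 3],
                   (S[, 1, 2] + S[, 2, 1]) / 2,
                   (S[, 1, 3] + S[, 3, 1]) / 2,
                   (S[, 2, 3] + S[, 3, 2]) / 2)
  } else {
    voigt <- matrix(as.numeric(vertex_stresses), ncol = 6)
  }
  if (nrow(voigt) != nrow(normals)) stop("stress/normal count mismatch")
  Tx <- voigt[, 1] * normals[, 1] + voigt[, 4] * normals[, 2] +
    voigt[, 5] * normals[, 3]
  Ty <- voigt[, 4] * normals[, 1] + voigt[, 2] * normals[, 2] +
    voigt[, 6] * normals[, 3]
  Tz <- voigt[, 5] * normals[, 1] + voigt[, 6] * normals[, 2] +
    voigt[, 3] * normals[, 3]
  Tr <- cbind(Tx, Ty, Tz)
  structure(list(vertices = vertices, normals = normals, traction = Tr,
                 magnitude = sqrt(Tx^2 + Ty^2 + Tz^2),
                 in_plane = sqrt(Tx^2 + Ty^2), out_of_plane = Tz,
                 triangles = triangles),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("<traction_field> %d vertices, peak |T| = %.4g Pa\n",
              nrow(x$traction), max(x$magnitude)))
  invisible(x)
}

#' Full surface-traction recovery from a forward solution
#'
#' Convenience wrapper chaining [project_stress_to_surface()],
#' [surface_normals()] and [compute_traction()].
#'
#' @param solution a [solve_forward()] result.
#' @return A `traction_field` (see [compute_traction()]); the reference
#'   vertex positions are attached as `ref_vertices`.
#' @export
surface_traction <- function(solution) {
  proj <- project_stress_to_surface(solution)
  sn <- surface_normals(proj$vertices, proj$dims)
  tf <- compute_traction(proj$vertex_stress, sn$normals,
                         vertices = proj$vertices, triangles = sn$triangles)
  tf$ref_vertices <- proj$ref_vertices
  tf$dims <- proj$dims
  tf
}

#' Integrate the traction field over the deformed top surface
#'
#' Net force transmitted through the surface, computed on the deformed
#' triangulation (consistent with Cauchy/true stress): per triangle the
#' mean of its vertex tractions times its deformed area.
#'
#' @param tf a `traction_field` carrying `vertices` and `triangles`.
#' @return Named numeric: force components `Fx`, `Fy`, `Fz` and magnitude
#'   `F` in nN (1 Pa um^2 = 1e-3 nN).
#' @export
integrate_traction <- function(tf) {
  stopifnot(inherits(tf, "traction_field"))
  if (is.null(tf$vertices) || is.null(tf$triangles))
    stop("traction field lacks geometry; use surface_traction()")
  tri <- tf$triangles
  v1 <- tf$vertices[tri[, 2], , drop = FALSE] - tf$vertices[tri[, 1], , drop = FALSE]
  v2 <- tf$vertices[tri[, 3], , drop = FALSE] - tf$vertices[tri[, 1], , drop = FALSE]
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  Tmean <- (tf$traction[tri[, 1], , drop = FALSE] +
              tf$traction[tri[, 2], , drop = FALSE] +
              tf$traction[tri[, 3], , drop = FALSE]) / 3
  Fvec <- unname(colSums(Tmean * area)) / 1000     # Pa um^2 -> nN
  c(Fx = Fvec[1], Fy = Fvec[2], Fz = Fvec[3],
    F = sqrt(sum(Fvec^2)))
}
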