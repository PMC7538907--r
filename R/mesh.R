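#' Hyperelastic material model from engineering constants
#'
#' Converts Young's modulus and Poisson's ratio to the Lame constants used
#' by the compressible neo-Hookean strain energy.
#'
#' @param E Young's modulus (Pa), `> 0`.
#' @param nu Poisson's ratio, `0 <= nu < 0.5` (the incompressible limit is
#'   not supported by the compressible formulation).
#' @return An object of class `material_model` with fields `E`, `nu`, `mu`
#'   and `lambda` (Pa).
#' @examples
#' make_material(1500, 0.45)   # mu ~ 517.24 Pa, lambda ~ 4655.17 Pa
#' @export
make_material <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("'E' must be positive (Pa)")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    stop("'nu' must satisfy 0 <= nu < 0.5 (incompressible limit unsupported)")
  structure(list(E = E, nu = nu,
                 mu = E / (2 * (1 + nu)),
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu))),
            class = "material_model")
}

#' Default configuration of the baseline hexahedral mesh
#'
#' The shipped defaults produce the 38 x 38 x 18 graded brick grid
#' (25,992 first-order hexahedral elements) used as the convergent baseline
#' for all forward solves, with element density following a Gaussian decay
#' away from the refinement centre (the region of the cell) and geometric
#' refinement towards the top surface where displacement gradients
#' concentrate.
#'
#' @param nx,ny,nz element counts per axis.
#' @param refine_center lateral refinement centre in unit coordinates.
#' @param refine_width Gaussian decay width of the element-density profile
#'   (unit coordinates).
#' @param refine_ratio centre-to-edge element density ratio (>= 1; 1 gives
#'   a uniform grid).
#' @param z_refine_ratio top-to-bottom element density ratio.
#' @return A list of class `mesh_config`.
#' @export
mesh_config <- function(nx = 38L, ny = 38L, nz = 18L,
                        refine_center = c(0.5, 0.5), refine_width = 1 / 6,
                        refine_ratio = 3, z_refine_ratio = 3) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, refine_width > 0,
            refine_ratio >= 1, z_refine_ratio >= 1)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), refine_center = refine_center,
                 refine_width = refine_width, refine_ratio = refine_ratio,
                 z_refine_ratio = z_refine_ratio),
            class = "mesh_config")
}

## graded 1D node positions on [0, 1]: element density follows rho(t),
## nodes are the equal-mass quantiles of rho
graded_nodes <- function(n_elem, rho) {
  tt <- seq(0, 1, length.out = 4096)
  dens <- rho(tt)
  cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(cdf, tt, xout = seq(0, 1, length.out = n_elem + 1),
                ties = "ordered")$y
}

#' Build the baseline graded hexahedral mesh
#'
#' Constructs a tensor-product mesh of first-order (trilinear) hexahedra on
#' the unit box `[0,1] x [0,1] x [-1,0]`, graded so the in-plane element
#' density decays as a Gaussian away from the refinement centre and the
#' axial density increases geometrically towards the top surface.  Use
#' [warp_mesh_to_volume()] to scale it to the physical image volume.  Face
#' sets (`left` x-min, `right` x-max, `back` y-min, `front` y-max, `bottom`
#' z-min, `top` z-max) are tagged by node id.
#'
#' @param config a [mesh_config()].
#' @return An object of class `hex_mesh`: node coordinates (`nodes`,
#'   n x 3), 8-column element connectivity (`conn`, 1-based, standard hex
#'   ordering), the tensor node coordinate vectors `xs`, `ys`, `zs`, face
#'   node-id sets (`faces`), and `n_elements`.
#' @examples
#' m <- build_base_mesh(mesh_config())
#' m$n_elements   # 25992
#' @export
build_base_mesh <- function(config = mesh_config()) {
  stopifnot(inherits(config, "mesh_config"))
  r <- config$refine_ratio
  w <- config$refine_width
  cx <- config$refine_center[1]; cy <- config$refine_center[2]
  xs <- graded_nodes(config$nx, function(t) 1 + (r - 1) * exp(-(t - cx)^2 / (2 * w^2)))
  ys <- graded_nodes(config$ny, function(t) 1 + (r - 1) * exp(-(t - cy)^2 / (2 * w^2)))
  zr <- config$z_refine_ratio
  zs <- graded_nodes(config$nz, function(t) zr^t) - 1   # density grows to top
  mesh <- tensor_hex_mesh(xs, ys, zs)
  jmin <- min(hex_jacobians(mesh))
  if (jmin <= 0) stop("mesh grading produced inverted elements")
  mesh$config <- config
  mesh
}

## assemble a tensor-product hex mesh from sorted axis node coordinates
tensor_hex_mesh <- function(xs, ys, zs) {
  nnx <- length(xs); nny <- length(ys); nnz <- length(zs)
  nodes <- cbind(rep(xs, times = nny * nnz),
                 rep(rep(ys, each = nnx), times = nnz),
                 rep(zs, each = nnx * nny))
  nid <- function(i, j, k) i + (j - 1L) * nnx + (k - 1L) * nnx * nny
  ex <- nnx - 1L; ey <- nny - 1L; ez <- nnz - 1L
  i <- rep(seq_len(ex), times = ey * ez)
  j <- rep(rep(seq_len(ey), each = ex), times = ez)
  k <- rep(seq_len(ez), each = ex * ey)
  conn <- cbind(nid(i, j, k), nid(i + 1L, j, k),
                nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  gi <- rep(seq_len(nnx), times = nny * nnz)
  gj <- rep(rep(seq_len(nny), each = nnx), times = nnz)
  gk <- rep(seq_len(nnz), each = nnx * nny)
  faces <- list(left = which(gi == 1L), right = which(gi == nnx),
                back = which(gj == 1L), front = which(gj == nny),
                bottom = which(gk == 1L), top = which(gk == nnz))
  structure(list(nodes = nodes, conn = conn, xs = xs, ys = ys, zs = zs,
                 faces = faces, n_elements = nrow(conn)),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d hexahedral elements, %d nodes (%d x %d x %d node grid)\n",
              x$n_elements, nrow(x$nodes), length(x$xs), length(x$ys),
              length(x$zs)))
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("  bounding box [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

## minimum corner Jacobian per element (positive for valid hexes); for the
## axis-aligned tensor meshes used here this reduces to products of edge
## lengths, but the general trilinear computation is kept for warped meshes
hex_jacobians <- function(mesh) {
  fem_min_jacobians(mesh$nodes, mesh$conn - 1L)
}

#' Warp a base mesh to fill the physical image volume
#'
#' Applies the per-axis affine map taking the mesh bounding box to the
#' target extents (anisotropic scaling plus offset).  Connectivity, element
#' count and face tags are preserved.
#'
#' @param mesh a [build_base_mesh()] result.
#' @param target_extents physical size `(Lx, Ly, Lz)` in um.
#' @param origin physical position (um) of the `(x-min, y-min, z-min)`
#'   corner; by default the top surface is placed at `z = 0` with the
#'   volume below it.
#' @return The warped `hex_mesh`.
#' @export
warp_mesh_to_volume <- function(mesh, target_extents,
                                origin = c(0, 0, -target_extents[3])) {
  stopifnot(inherits(mesh, "hex_mesh"))
  target_extents <- as.numeric(target_extents)
  if (any(!is.finite(target_extents)) || any(target_extents <= 0))
    stop("degenerate target extents")
  out <- mesh
  for (ax in 1:3) {
    r <- range(mesh$nodes[, ax])
    sc <- target_extents[ax] / diff(r)
    out$nodes[, ax] <- (mesh$nodes[, ax] - r[1]) * sc + origin[ax]
  }
  out$xs <- sort(unique(out$nodes[out$faces$top, 1]))
  out$ys <- sort(unique(out$nodes[out$faces$top, 2]))
  out$zs <- (mesh$zs - min(mesh$zs)) / diff(range(mesh$zs)) *
    target_extents[3] + origin[3]
  out
}

#' Planarization grid taken from the FE top surface
#'
#' Returns the in-plane node coordinates of the mesh top surface, the
#' single source of truth shared by [regularized_resample()] and
#' [solve_forward()]: the planarized displacement grid is, node for node,
#' the FE top-surface mesh.
#'
#' @param mesh a warped `hex_mesh`.
#' @return List with sorted node coordinate vectors `x` and `y` (um).
#' @export
top_surface_grid <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  list(x = mesh$xs, y = mesh$ys)
}
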