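#' Reject out-of-plane bead outliers by z-height
#'
#' Beads further than `n_std` standard deviations from the mean bead
#' z-height are removed before plane fitting.  With the single-layer bead
#' preparation such outliers are rare, isolated, and noisier than the
#' dominant layer.
#'
#' @param field a `scattered_displacement_field` (or any data.frame with a
#'   `z` column).
#' @param n_std number of standard deviations tolerated.
#' @return The filtered field, with attribute `n_removed`.
#' @export
reject_z_outliers <- function(field, n_std = 3) {
  if (nrow(field) < 10L) stop("need at least 10 beads for z-outlier rejection")
  if (n_std <= 0) stop("'n_std' must be positive")
  mz <- mean(field$z); sz <- stats::sd(field$z)
  keep <- if (sz == 0) rep(TRUE, nrow(field)) else
    abs(field$z - mz) <= n_std * sz
  if (!any(keep))
    stop("all beads removed: n_std too aggressive for this z-distribution")
  out <- field[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(field)
  out
}

#' Total-least-squares best-fit plane of bead locations
#'
#' Fits the plane minimizing orthogonal distances (principal component
#' analysis of the centred positions); the returned normal is oriented
#' towards +z, and the two in-plane axes are orthonormal, with the first
#' chosen as close as possible to the global x axis.  Fitting the bead
#' plane corrects for any tilt of the stage or gel surface relative to the
#' imaging coordinates.
#'
#' @param beads a `bead_set` or data.frame with `x`, `y`, `z` columns.
#' @return An object of class `fitted_plane`: list with `point` (centroid),
#'   unit `normal`, and in-plane axes `e1`, `e2`.
#' @export
fit_plane <- function(beads) {
  P <- cbind(beads$x, beads$y, beads$z)
  if (nrow(P) < 3L) stop("need at least 3 beads to fit a plane")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) bead configuration: plane undefined")
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n
  if (n[3] == 0) stop("degenerate vertical plane: beads are not a surface layer")
  e1 <- c(1, 0, 0) - n[1] * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  structure(list(point = ctr, normal = n, e1 = e1, e2 = e2),
            class = "fitted_plane")
}

#' @export
print.fitted_plane <- function(x, ...) {
  cat(sprintf("<fitted_plane> point (%.3g, %.3g, %.3g) um, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' In-plane coordinates of 3D points relative to a fitted plane
#'
#' @param plane a [fit_plane()] result.
#' @param xyz n x 3 matrix of positions (um).
#' @return n x 3 matrix of `(xi, eta, zeta)` plane coordinates: two
#'   in-plane components and the signed normal offset.
#' @export
plane_coords <- function(plane, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  rc <- sweep(xyz, 2, plane$point)
  cbind(rc %*% plane$e1, rc %*% plane$e2, rc %*% plane$normal)
}

#' Resample scattered displacements onto a regular grid by curvature
#' regularization
#'
#' For each displacement component `u` the gridded field minimizes
#' `sum_beads (u(p_b) - u_b)^2 + lambda * hbar^4 * Int |D2 u|^2 dA`,
#' where `u(p_b)` interpolates the grid bilinearly at the bead's projected
#' in-plane position and the discrete thin-plate integral collects the
#' (possibly non-uniform) second finite differences `u_xx`, `u_yy` and
#' `sqrt(2) u_xy` with local cell-area quadrature weights; `hbar` is the
#' mean grid spacing, making `lambda` dimensionless (grid units).  The penalty null space
#' is the affine fields, which are therefore reproduced exactly for any
#' `lambda`; in regions without bead support the regularizer extrapolates
#' (flagged in the report).  In-plane components share `lambda_xy`; the
#' out-of-plane component uses `lambda_z`.
#'
#' @param field a `scattered_displacement_field`.
#' @param plane a [fit_plane()] result defining the grid plane.
#' @param grid_spec list with sorted node coordinates `x` and `y` (um, in
#'   plane coordinates); use [top_surface_grid()] to take them from the FE
#'   mesh so grid and mesh nodes coincide exactly.
#' @param lambda_xy,lambda_z dimensionless smoothing coefficients.
#' @return A `planar_displacement_grid`: list with node coordinate vectors
#'   `x`, `y`, displacement matrices `ux`, `uy`, `uz` (length(x) by
#'   length(y), global components, um), the `plane`, the lambdas, and a
#'   `report` with the fraction of nodes without direct data support.
#' @export
regularized_resample <- function(field, plane, grid_spec,
                                 lambda_xy = 1e-3, lambda_z = 1e-3) {
  if (lambda_xy < 0 || lambda_z < 0) stop("lambdas must be >= 0")
  gx <- sort(as.numeric(grid_spec$x)); gy <- sort(as.numeric(grid_spec$y))
  nx <- length(gx); ny <- length(gy)
  if (nx < 4L || ny < 4L) stop("grid must have at least 4 nodes per axis")
  pc <- plane_coords(plane, cbind(field$x, field$y, field$z))
  px <- pc[, 1]; py <- pc[, 2]
  inside <- px >= gx[1] - 1e-9 & px <= gx[nx] + 1e-9 &
    py >= gy[1] - 1e-9 & py <= gy[ny] + 1e-9
  if (!all(inside)) {
    warning(sprintf("%d bead(s) outside the grid dropped", sum(!inside)))
    px <- px[inside]; py <- py[inside]
  }
  ub <- cbind(field$ux, field$uy, field$uz)[inside, , drop = FALSE]
  if (length(px) < 3L) stop("grid does not cover the scattered data")
  A <- bilinear_matrix(gx, gy, px, py)
  P2 <- curvature_penalty(gx, gy)
  AtA <- Matrix::crossprod(A)
  occupied <- Matrix::colSums(A) > 0
  grids <- vector("list", 3)
  for (c in 1:3) {
    lam <- if (c == 3) lambda_z else lambda_xy
    M <- AtA + lam * P2
    rhs <- Matrix::crossprod(A, ub[, c])
    sol <- as.numeric(Matrix::solve(M, rhs))
    grids[[c]] <- matrix(sol, nx, ny)
  }
  structure(list(x = gx, y = gy, ux = grids[[1]], uy = grids[[2]],
                 uz = grids[[3]], plane = plane,
                 lambda_xy = lambda_xy, lambda_z = lambda_z,
                 report = list(n_beads = length(px),
                               frac_unsupported = mean(!occupied))),
            class = "planar_displacement_grid")
}

#' @export
print.planar_displacement_grid <- function(x, ...) {
  cat(sprintf("<planar_displacement_grid> %d x %d nodes, max |u| = %.4g um\n",
              length(x$x), length(x$y),
              max(sqrt(x$ux^2 + x$uy^2 + x$uz^2))))
  invisible(x)
}

## sparse bilinear interpolation matrix from a tensor grid to points
bilinear_matrix <- function(gx, gy, px, py) {
  nx <- length(gx); ny <- length(gy); n <- length(px)
  ix <- pmin(pmax(findInterval(px, gx), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(py, gy), 1L), ny - 1L)
  tx <- (px - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (py - gy[iy]) / (gy[iy + 1] - gy[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  node <- function(i, j) i + (j - 1L) * nx
  ii <- rep(seq_len(n), 4)
  jj <- c(node(ix, iy), node(ix + 1L, iy), node(ix, iy + 1L),
          node(ix + 1L, iy + 1L))
  xx <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, nx * ny))
}

## second-difference stencil weights for non-uniform 1D nodes
## (3-point approximation of u'' exact for quadratics)
second_diff_weights <- function(g) {
  n <- length(g)
  h1 <- g[2:(n - 1)] - g[1:(n - 2)]
  h2 <- g[3:n] - g[2:(n - 1)]
  list(wl = 2 / (h1 * (h1 + h2)), wc = -2 / (h1 * h2),
       wr = 2 / (h2 * (h1 + h2)))
}

## discrete thin-plate penalty matrix: the curvature integral
## Int (u_xx^2 + 2 u_xy^2 + u_yy^2) dA discretized with non-uniform
## second-difference stencils and local cell-area quadrature weights, then
## scaled by hbar^4 so that lambda is dimensionless ("grid units")
curvature_penalty <- function(gx, gy) {
  nx <- length(gx); ny <- length(gy)
  hbar <- (mean(diff(gx)) + mean(diff(gy))) / 2
  node <- function(i, j) i + (j - 1L) * nx
  ## nodal quadrature lengths (half-interval on each side; one-sided at
  ## the boundary)
  nodal_len <- function(g) {
    n <- length(g)
    c(g[2] - g[1], (g[3:n] - g[1:(n - 2)]) / 2, g[n] - g[n - 1])
  }
  ax <- nodal_len(gx); ay <- nodal_len(gy)
  ## u_xx at interior-x nodes, all y
  wx <- second_diff_weights(gx)
  i_int <- 2:(nx - 1)
  rows <- length(i_int) * ny
  Ii <- rep(seq_len(rows), 3)
  base_i <- rep(i_int, times = ny); base_j <- rep(seq_len(ny), each = nx - 2)
  sq <- sqrt(ax[base_i] * ay[base_j])
  Jx <- c(node(base_i - 1L, base_j), node(base_i, base_j),
          node(base_i + 1L, base_j))
  Xx <- c(rep(wx$wl, times = ny), rep(wx$wc, times = ny),
          rep(wx$wr, times = ny)) * rep(sq, 3)
  Dxx <- Matrix::sparseMatrix(i = Ii, j = Jx, x = Xx,
                              dims = c(rows, nx * ny))
  ## u_yy at interior-y nodes, all x
  wy <- second_diff_weights(gy)
  j_int <- 2:(ny - 1)
  rows <- nx * length(j_int)
  Ii <- rep(seq_len(rows), 3)
  base_i <- rep(seq_len(nx), times = ny - 2); base_j <- rep(j_int, each = nx)
  sq <- sqrt(ax[base_i] * ay[base_j])
  wyl <- rep(wy$wl, each = nx); wyc <- rep(wy$wc, each = nx)
  wyr <- rep(wy$wr, each = nx)
  Jy <- c(node(base_i, base_j - 1L), node(base_i, base_j),
          node(base_i, base_j + 1L))
  Dyy <- Matrix::sparseMatrix(i = Ii, j = Jy,
                              x = c(wyl, wyc, wyr) * rep(sq, 3),
                              dims = c(rows, nx * ny))
  ## u_xy on cell centres (first differences in each direction)
  ci <- seq_len(nx - 1); cj <- seq_len(ny - 1)
  rows <- (nx - 1) * (ny - 1)
  bi <- rep(ci, times = ny - 1); bj <- rep(cj, each = nx - 1)
  hx <- (gx[bi + 1] - gx[bi]); hy <- (gy[bj + 1] - gy[bj])
  w <- sqrt(hx * hy) / (hx * hy)
  Ii <- rep(seq_len(rows), 4)
  Jc <- c(node(bi, bj), node(bi + 1L, bj), node(bi, bj + 1L),
          node(bi + 1L, bj + 1L))
  Xc <- c(w, -w, -w, w)
  Dxy <- Matrix::sparseMatrix(i = Ii, j = Jc, x = Xc,
                              dims = c(rows, nx * ny))
  hbar^4 * (Matrix::crossprod(Dxx) + Matrix::crossprod(Dyy) +
              2 * Matrix::crossprod(Dxy))
}
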