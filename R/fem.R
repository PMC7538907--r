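#' Neo-Hookean strain energy density
#'
#' Evaluates the compressible neo-Hookean strain energy
#' `Psi = mu/2 (tr C - 3) - mu ln J + lambda/2 (ln J)^2` for a deformation
#' gradient `F`, with `C = F'F` and `J = det F`.  The `mu ln J` term makes
#' the reference configuration stress-free (`Psi = 0`, `sigma = 0` at
#' `F = I`), which a volumetric term without the `mu` coefficient would
#' not; see the methods vignette for the discussion of this form.
#'
#' @param F 3 x 3 deformation gradient with `det F > 0`.
#' @param material a [make_material()].
#' @return Strain energy density (Pa).
#' @examples
#' m <- make_material(1500, 0.45)
#' strain_energy_density(diag(3), m)                  # 0
#' strain_energy_density(diag(c(1.1, 1, 1)), m)       # ~26.16 Pa
#' @export
strain_energy_density <- function(F, material) {
  stopifnot(inherits(material, "material_model"))
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (J <= 0) stop("J = det(F) must be positive (inverted deformation)")
  C <- crossprod(F)
  material$mu / 2 * (sum(diag(C)) - 3) - material$mu * log(J) +
    material$lambda / 2 * log(J)^2
}

#' Solve the substrate boundary-value problem
#'
#' Static finite-strain equilibrium of the compressible neo-Hookean
#' substrate under the measured top-surface Dirichlet condition.  Default
#' face constraints follow the standard scheme for this geometry: the left
#' face is fixed in x (`u_x = 0`), the back face in y (`u_y = 0`), the
#' bottom face in all components, and the top surface carries the
#' planarized 3D displacement vectors.  The nonlinear system is solved by
#' Newton iteration (sparse Cholesky) with automatic load stepping on
#' non-convergence; elements use F-bar volumetric sampling against locking.
#'
#' @param mesh a warped [build_base_mesh()] mesh whose top-surface nodes
#'   coincide with the boundary-condition grid nodes.
#' @param material a [make_material()].
#' @param top_bc a `planar_displacement_grid` from
#'   [regularized_resample()], or a `length(xs) x length(ys) x 3` array of
#'   top-node displacements (um), or `NULL` when `extra_bc` fully defines
#'   the problem.
#' @param extra_bc optional list of additional Dirichlet specs, each a list
#'   `(nodes, comp, value)` (node ids, component 1..3, prescribed value);
#'   overrides the defaults on those dofs.
#' @param formulation `"neohookean"` (finite strain, default) or
#'   `"linear"` (one tangent solve about the reference state: exact
#'   linear elasticity with the same E, nu).
#' @param rtol relative residual tolerance of the Newton iteration.
#' @param max_iter maximum Newton iterations per load step.
#' @param max_steps maximum load increments tried on non-convergence.
#' @return An object of class `field_solution`: nodal displacements `u`
#'   (n x 3, um), `deformed` nodal coordinates, per-quadrature-point
#'   Cauchy stresses `qp` (with positions and J), the `mesh`, `material`,
#'   and a solver `report` (residual history per step).
#' @export
solve_forward <- function(mesh, material, top_bc = NULL, extra_bc = list(),
                          formulation = c("neohookean", "linear"),
                          rtol = 1e-8, max_iter = 25L, max_steps = 10L) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(material, "material_model"))
  formulation <- match.arg(formulation)
  nn <- nrow(mesh$nodes)
  conn0 <- mesh$conn - 1L
  ## assemble the prescribed-dof table ------------------------------------
  fixed <- logical(3L * nn)
  value <- numeric(3L * nn)
  dof <- function(nodes, comp) 3L * (nodes - 1L) + comp
  set_bc <- function(nodes, comp, vals) {
    d <- dof(nodes, comp)
    fixed[d] <<- TRUE
    value[d] <<- vals
  }
  set_bc(mesh$faces$left, 1L, 0)
  set_bc(mesh$faces$back, 2L, 0)
  for (c in 1:3) set_bc(mesh$faces$bottom, c, 0)
  if (!is.null(top_bc)) {
    ubc <- top_bc_array(mesh, top_bc)
    top <- mesh$faces$top
    ## top nodes are ordered x-fastest then y, matching the grid layout
    for (c in 1:3) set_bc(top, c, as.vector(ubc[, , c]))
  }
  for (bc in extra_bc) set_bc(bc$nodes, bc$comp, bc$value)
  free <- which(!fixed)
  pres <- which(fixed)

  u <- matrix(0, nn, 3)
  mu <- material$mu; la <- material$lambda
  report <- list(steps = list(), formulation = formulation)

  if (formulation == "linear") {
    asm <- fem_assemble(mesh$nodes, conn0, u * 0, mu, la, fbar = TRUE,
                        want_tangent = TRUE)
    K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kx,
                              dims = c(3 * nn, 3 * nn))
    uf <- numeric(3 * nn)
    uf[pres] <- value[pres]
    rhs <- -(K %*% uf)[free]
    uf[free] <- as.numeric(solve_spd(K[free, free, drop = FALSE], rhs))
    u <- t(matrix(uf, 3, nn))
    report$steps <- list(list(iterations = 1L, residuals = NA_real_))
  } else {
    ## the tangent's sparsity pattern is fixed, so the triplet-to-slot
    ## aggregation map and the symbolic factorization are built once
    kmap <- NULL
    n_steps <- 1L
    repeat {
      u <- matrix(0, nn, 3)
      ok_all <- TRUE
      report$steps <- list()
      for (s in seq_len(n_steps)) {
        alpha <- s / n_steps
        uf <- as.vector(t(u))
        uf[pres] <- alpha * value[pres]
        u <- t(matrix(uf, 3, nn))
        res_hist <- numeric(0)
        converged <- FALSE
        r0 <- NA_real_
        for (it in seq_len(max_iter)) {
          asm <- fem_assemble(mesh$nodes, conn0, u, mu, la, fbar = TRUE,
                              want_tangent = TRUE,
                              want_indices = is.null(kmap))
          if (!isTRUE(asm$ok)) { ok_all <- FALSE; break }
          r <- -asm$f[free]
          rn <- sqrt(sum(r^2))
          res_hist <- c(res_hist, rn)
          if (it == 1L) r0 <- max(rn, 1e-300)
          if (rn <= rtol * r0 || rn < 1e-12) { converged <- TRUE; break }
          if (is.null(kmap)) {
            K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kx,
                                      dims = c(3 * nn, 3 * nn))
            o <- order(asm$Kj, asm$Ki)       # dgC slot order
            same <- c(FALSE, diff(asm$Kj[o]) == 0 & diff(asm$Ki[o]) == 0)
            kmap <- list(K = K, o = o, grp = cumsum(!same))
          } else {
            K <- kmap$K
            K@x <- as.numeric(rowsum(asm$Kx[kmap$o], kmap$grp,
                                     reorder = FALSE))
          }
          rm(asm)
          du <- as.numeric(solve_spd(K[free, free, drop = FALSE], r))
          uf <- as.vector(t(u))
          uf[free] <- uf[free] + du
          u <- t(matrix(uf, 3, nn))
        }
        report$steps[[s]] <- list(iterations = length(res_hist),
                                  residuals = res_hist)
        if (!converged) { ok_all <- FALSE; break }
      }
      if (ok_all) break
      n_steps <- n_steps * 2L
      if (n_steps > max_steps)
        stop("Newton iteration failed to converge; residual history: ",
             paste(signif(utils::tail(report$steps[[length(report$steps)]]$residuals, 5), 3),
                   collapse = ", "))
    }
    report$n_steps <- n_steps
    rm(kmap)
    gc(verbose = FALSE)
  }

  qp <- fem_qp_stress(mesh$nodes, conn0, u, mu, la, fbar = TRUE)
  structure(list(u = u, deformed = mesh$nodes + u, qp = qp, mesh = mesh,
                 material = material, report = report,
                 fixed = fixed, bc_value = value),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d nodes, max |u| = %.4g um, %s formulation\n",
              nrow(x$u), max(sqrt(rowSums(x$u^2))), x$report$formulation))
  invisible(x)
}

## convert a planar grid / array BC to an (nx, ny, 3) array matching the
## top-surface node layout, verifying the hand-off contract
top_bc_array <- function(mesh, top_bc) {
  nxn <- length(mesh$xs); nyn <- length(mesh$ys)
  if (inherits(top_bc, "planar_displacement_grid")) {
    if (length(top_bc$x) != nxn || length(top_bc$y) != nyn ||
        max(abs(top_bc$x - mesh$xs)) > 1e-6 ||
        max(abs(top_bc$y - mesh$ys)) > 1e-6)
      stop("boundary-condition grid does not match the mesh top-surface nodes")
    arr <- array(0, c(nxn, nyn, 3))
    arr[, , 1] <- top_bc$ux; arr[, , 2] <- top_bc$uy; arr[, , 3] <- top_bc$uz
    return(arr)
  }
  if (is.array(top_bc) && length(dim(top_bc)) == 3L &&
      all(dim(top_bc) == c(nxn, nyn, 3)))
    return(top_bc)
  stop("'top_bc' must be a planar_displacement_grid or an (nx, ny, 3) array")
}

## sparse symmetric solve: supernodal Cholesky, retried with increasing
## diagonal shifts if a tangent transiently loses positive definiteness
## mid-Newton (a shifted tangent still yields a descent-like update and
## costs far less than a sparse LU at this size)
solve_spd <- function(K, b) {
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  try_chol <- function(M) {
    tryCatch(suppressWarnings(Matrix::Cholesky(M, LDL = FALSE,
                                               super = TRUE)),
             error = function(e) NULL)
  }
  ch <- try_chol(K)
  if (!is.null(ch)) return(Matrix::solve(ch, b))
  dscale <- mean(abs(Matrix::diag(K)))
  for (tau in 10^c(-8, -6, -4, -2)) {
    ch <- try_chol(K + tau * dscale * Matrix::Diagonal(nrow(K)))
    if (!is.null(ch)) return(Matrix::solve(ch, b))
  }
  Matrix::solve(K, b)
}
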