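test_that("the Cauchy relation extracts hydrostatic and shear rows correctly", {
  n <- rbind(c(0, 0, 1), c(0, 0, 1))
  ## hydrostatic p I and a pure sigma_xz state, in Voigt order
  vo <- rbind(c(50, 50, 50, 0, 0, 0),
              c(0, 0, 0, 0, 100, 0))
  tf <- compute_traction(vo, n)
  expect_equal(tf$traction[1, ], c(0, 0, 50), ignore_attr = TRUE)
  expect_equal(tf$traction[2, ], c(100, 0, 0), ignore_attr = TRUE)
  expect_equal(tf$out_of_plane, c(50, 0))
  expect_equal(tf$in_plane, c(0, 100))
})

test_that("non-symmetric stress tensors and non-unit normals are rejected", {
  S <- array(0, c(1, 3, 3))
  S[1, , ] <- rbind(c(1, 5, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(compute_traction(S, rbind(c(0, 0, 1))), "non-symmetric")
  expect_error(compute_traction(rbind(rep(1, 6)), rbind(c(0, 0, 2))),
               "unit")
  ## symmetric full tensors are accepted
  S[1, , ] <- rbind(c(1, 2, 3), c(2, 4, 5), c(3, 5, 6))
  tf <- compute_traction(S, rbind(c(0, 0, 1)))
  expect_equal(tf$traction[1, ], c(3, 5, 6), ignore_attr = TRUE)
})

test_that("surface normals are exact for flat and rigidly tilted grids", {
  gx <- seq(0, 10, length.out = 8); gy <- seq(0, 12, length.out = 9)
  V <- cbind(rep(gx, times = 9), rep(gy, each = 8), 0)
  sn <- surface_normals(V, c(8, 9))
  expect_equal(sn$normals, matrix(rep(c(0, 0, 1), each = 72), 72),
               tolerance = 1e-12)
  th <- 0.15
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  V2 <- V %*% t(R)
  sn2 <- surface_normals(V2, c(8, 9))
  ## rotation about y maps (0,0,1) to (sin th, 0, cos th)
  expect_equal(sn2$normals,
               matrix(rep(c(sin(th), 0, cos(th)), each = 72), 72),
               tolerance = 1e-9)
  expect_error(surface_normals(cbind(1:5, 1, 0), c(5, 1)), "collinear")
})

test_that("normals tilt toward the centre of a Gaussian indentation, axisymmetrically", {
  gx <- seq(-10, 10, length.out = 21)
  V <- cbind(rep(gx, times = 21), rep(gx, each = 21), 0)
  r2 <- V[, 1]^2 + V[, 2]^2
  V[, 3] <- -0.5 * exp(-r2 / 20)
  sn <- surface_normals(V, c(21, 21))
  ## analytic surface gradient: n ~ (-dz/dx, -dz/dy, 1)
  gzx <- 0.5 * (2 * V[, 1] / 20) * exp(-r2 / 20)
  inward <- -(sn$normals[, 1] * V[, 1] + sn$normals[, 2] * V[, 2])
  off_ctr <- r2 > 4 & r2 < 64
  expect_true(all(inward[off_ctr] > 0))     # tilt towards the indentation
  ## mirror symmetry of the normal field
  nmat <- matrix(sn$normals[, 1], 21, 21)
  expect_equal(nmat, -nmat[21:1, ], tolerance = 1e-9)
})

test_that("stress projection reproduces constant and linear-in-x fields exactly", {
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(5, 4, 3, refine_ratio = 1,
                                z_refine_ratio = 1)),
    c(10, 8, 6), origin = c(0, 0, -6))
  m <- make_material(1000, 0.3)
  u0 <- matrix(0, nrow(mesh$nodes), 3)
  qp <- eftfm:::fem_qp_stress(mesh$nodes, mesh$conn - 1L, u0, m$mu,
                              m$lambda, TRUE)
  fake <- structure(list(mesh = mesh, qp = qp,
                         deformed = mesh$nodes,
                         u = u0), class = "field_solution")
  ## constant field
  fake$qp$sigma <- matrix(rep(c(7, 1, 2, 3, 4, 5),
                              each = nrow(qp$sigma)),
                          nrow(qp$sigma))
  pr <- project_stress_to_surface(fake)
  for (c in 1:6)
    expect_equal(pr$vertex_stress[, c],
                 rep(c(7, 1, 2, 3, 4, 5)[c], nrow(pr$vertex_stress)),
                 tolerance = 1e-9)
  ## sigma_zz = 2 + 3 x, linear ramp
  fake$qp$sigma <- matrix(0, nrow(qp$sigma), 6)
  fake$qp$sigma[, 3] <- 2 + 3 * qp$x[, 1]
  pr2 <- project_stress_to_surface(fake)
  expect_equal(pr2$vertex_stress[, 3], 2 + 3 * pr2$vertices[, 1],
               tolerance = 1e-6)
})

test_that("integrating a uniform traction over a flat surface gives pressure times area", {
  gx <- seq(0, 10, length.out = 6); gy <- seq(0, 20, length.out = 11)
  V <- cbind(rep(gx, times = 11), rep(gy, each = 6), 0)
  sn <- surface_normals(V, c(6, 11))
  vo <- matrix(0, 66, 6); vo[, 3] <- 250
  tf <- compute_traction(vo, sn$normals, vertices = V,
                         triangles = sn$triangles)
  Fint <- integrate_traction(tf)
  expect_equal(unname(Fint["Fz"]), 250 * 200 / 1000, tolerance = 1e-9)
  expect_equal(unname(Fint["Fx"]), 0, tolerance = 1e-12)
})

test_that("surface traction is linear in the applied load in the small-strain regime", {
  sub <- elastic_substrate(1500, 0.45, depth = 20)
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(10, 10, 6)), c(30, 30, 20),
    origin = c(0, 0, -20))
  smp <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(8, sub, peak_disp = 1e-3, center = c(15, 15)),
    1, 15, periodic_cell = 30)
  xy <- cbind(rep(mesh$xs, times = length(mesh$ys)),
              rep(mesh$ys, each = length(mesh$xs)))
  u <- smp$u(xy)
  mk <- function(scale) {
    a <- array(0, c(length(mesh$xs), length(mesh$ys), 3))
    a[, , 1] <- scale * u[, 1]; a[, , 2] <- scale * u[, 2]
    a[, , 3] <- scale * u[, 3]
    a
  }
  m <- make_material(1500, 0.45)
  t1 <- surface_traction(solve_forward(mesh, m, mk(1)))$traction
  t2 <- surface_traction(solve_forward(mesh, m, mk(2)))$traction
  expect_equal(t2, 2 * t1, tolerance = 0.01)
})
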