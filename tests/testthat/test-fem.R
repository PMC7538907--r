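test_that("Lame constants follow the standard conversions", {
  m <- make_material(1500, 0.45)
  expect_equal(m$mu, 517.2414, tolerance = 1e-6)
  expect_equal(m$lambda, 4655.172, tolerance = 1e-6)
  m0 <- make_material(1500, 0)
  expect_equal(m0$mu, 750)
  expect_equal(m0$lambda, 0)
  expect_error(make_material(1500, 0.5), "nu")
  expect_error(make_material(-1, 0.3), "positive")
})

test_that("strain energy density matches hand-evaluated values and objectivity", {
  m <- make_material(1500, 0.45)
  expect_equal(strain_energy_density(diag(3), m), 0)
  expect_equal(strain_energy_density(diag(c(1.1, 1, 1)), m), 26.1558,
               tolerance = 1e-4)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(strain_energy_density(R, m), 0, tolerance = 1e-12)
  expect_error(strain_energy_density(diag(c(-1, 1, 1)), m), "positive")
})

test_that("the shipped default mesh has the baseline element count, quickly", {
  t0 <- proc.time()[3]
  m <- build_base_mesh(mesh_config())
  expect_equal(m$n_elements, 25992L)
  expect_lt(proc.time()[3] - t0, 5)
  expect_gt(min(eftfm:::hex_jacobians(m)), 0)
  ## uniform counting case
  m2 <- build_base_mesh(mesh_config(nx = 10, ny = 10, nz = 5,
                                    refine_ratio = 1, z_refine_ratio = 1))
  expect_equal(m2$n_elements, 500L)
})

test_that("warping preserves connectivity and scales coordinates per axis", {
  m <- build_base_mesh(mesh_config(nx = 6, ny = 5, nz = 4))
  w1 <- warp_mesh_to_volume(m, c(1, 1, 1), origin = c(0, 0, -1))
  expect_equal(w1$nodes, m$nodes, tolerance = 1e-12)
  w2 <- warp_mesh_to_volume(m, c(2, 1, 1), origin = c(0, 0, -1))
  expect_equal(w2$nodes[, 1], 2 * m$nodes[, 1], tolerance = 1e-12)
  expect_identical(w2$conn, m$conn)
  expect_identical(w2$faces, m$faces)
  w3 <- warp_mesh_to_volume(m, c(1.3, 0.8, 2.0), origin = c(0, 0, -2))
  expect_gt(min(eftfm:::hex_jacobians(w3)), 0)
  expect_error(warp_mesh_to_volume(m, c(0, 1, 1)), "degenerate")
})

test_that("confined uniaxial compression passes the patch test exactly", {
  m <- make_material(1500, 0.3)
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(4, 4, 4, refine_ratio = 1,
                                z_refine_ratio = 1)),
    c(10, 10, 10), origin = c(0, 0, -10))
  delta <- 0.5
  extra <- list(
    list(nodes = mesh$faces$left, comp = 1L, value = 0),
    list(nodes = mesh$faces$right, comp = 1L, value = 0),
    list(nodes = mesh$faces$back, comp = 2L, value = 0),
    list(nodes = mesh$faces$front, comp = 2L, value = 0),
    list(nodes = mesh$faces$top, comp = 3L, value = -delta))
  sol <- solve_forward(mesh, m, top_bc = NULL, extra_bc = extra)
  sig <- sol$qp$sigma
  ## homogeneous closed form: F = diag(1, 1, 1 - delta/h)
  J <- 1 - delta / 10
  szz <- m$mu / J * (J^2 - 1) + m$lambda * log(J) / J
  sxx <- m$lambda * log(J) / J
  expect_lt(diff(range(sig[, 3])) / abs(szz), 1e-6)
  expect_equal(mean(sig[, 3]), szz, tolerance = 1e-9)
  expect_equal(mean(sig[, 1]), sxx, tolerance = 1e-9)
  expect_lt(max(abs(sig[, 4:6])), 1e-9 * abs(szz))
})

test_that("zero boundary displacement yields zero displacement and stress", {
  m <- make_material(1500, 0.45)
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(5, 5, 3)), c(20, 20, 10),
    origin = c(0, 0, -10))
  arr <- array(0, c(length(mesh$xs), length(mesh$ys), 3))
  sol <- solve_forward(mesh, m, top_bc = arr)
  expect_lt(max(abs(sol$u)), 1e-12)
  tf <- surface_traction(sol)
  expect_lt(max(tf$magnitude), 1e-6 * m$mu)
})

test_that("a rotated single element is stress free (frame indifference)", {
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(1, 1, 1, refine_ratio = 1,
                                z_refine_ratio = 1)),
    c(1, 1, 1), origin = c(0, 0, -1))
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  u <- mesh$nodes %*% t(R) - mesh$nodes
  m <- make_material(1500, 0.45)
  qp <- eftfm:::fem_qp_stress(mesh$nodes, mesh$conn - 1L, u, m$mu, m$lambda,
                              TRUE)
  expect_lt(max(abs(qp$sigma)), 1e-9 * m$mu)
  expect_lt(max(abs(qp$psi)), 1e-9 * m$mu)
  expect_equal(qp$J, rep(1, 8), tolerance = 1e-12)
})

test_that("small-strain neo-Hookean agrees with linear elasticity within 0.5%", {
  sub <- elastic_substrate(1500, 0.45, depth = 20)
  sc <- gaussian_traction_scene(8, sub, peak_disp = 2e-3, center = c(15, 15))
  smp <- boussinesq_gaussian_sampler(sc, 1, 15, periodic_cell = 30)
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(12, 12, 8)), c(30, 30, 20),
    origin = c(0, 0, -20))
  xy <- cbind(rep(mesh$xs, times = length(mesh$ys)),
              rep(mesh$ys, each = length(mesh$xs)))
  u <- smp$u(xy)
  arr <- array(0, c(length(mesh$xs), length(mesh$ys), 3))
  arr[, , 1] <- u[, 1]; arr[, , 2] <- u[, 2]; arr[, , 3] <- u[, 3]
  m <- make_material(1500, 0.45)
  s_nh <- solve_forward(mesh, m, arr, formulation = "neohookean")
  s_li <- solve_forward(mesh, m, arr, formulation = "linear")
  denom <- max(sqrt(rowSums(s_li$u^2)))
  expect_lt(max(abs(s_nh$u - s_li$u)) / denom, 0.005)
})

test_that("boundary-condition/mesh mismatches are rejected", {
  mesh <- warp_mesh_to_volume(
    build_base_mesh(mesh_config(5, 5, 3)), c(20, 20, 10),
    origin = c(0, 0, -10))
  m <- make_material(1500, 0.45)
  bad <- array(0, c(3, 3, 3))
  expect_error(solve_forward(mesh, m, bad), "planar_displacement_grid")
  grid <- structure(list(x = 1:6, y = 1:6,
                         ux = matrix(0, 6, 6), uy = matrix(0, 6, 6),
                         uz = matrix(0, 6, 6)),
                    class = "planar_displacement_grid")
  expect_error(solve_forward(mesh, m, grid), "does not match")
})
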