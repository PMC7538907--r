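test_that("half-space sampler matches its closed-form normalization and the point-load far field", {
  sub <- elastic_substrate(1500, 0.45)
  sc <- gaussian_traction_scene(10.24, sub, F_amp = 40)
  smp <- boussinesq_gaussian_sampler(sc, 10.24 / 8, 110)
  s <- sc$sigma
  ## peak displacement: u_z(0) = (1 - nu^2) t0 s sqrt(2 pi) / E
  t0 <- 40 * 1000 / (2 * pi * s^2)
  expect_equal(smp$t0, t0, tolerance = 1e-12)
  peak <- (1 - 0.45^2) * t0 * s * sqrt(2 * pi) / 1500
  expect_equal(smp$peak_disp, peak, tolerance = 1e-10)
  expect_equal(unname(smp$u(cbind(0, 0))[3]), peak, tolerance = 1e-10)
  ## far field approaches the Boussinesq point-load limit u_z = F(1-nu^2)/(pi E r)
  r <- 10 * 10.24
  uz <- smp$u(cbind(r, 0))[3]
  point <- 40e-9 * (1 - 0.45^2) / (pi * 1500 * r * 1e-6) * 1e6
  expect_lt(abs(uz - point) / point, 0.05)
  ## traction decays below 1% of peak by 5 W (displacement does not: 1/r tail)
  expect_lt(smp$t(cbind(5 * 10.24, 0))[3], 0.01 * smp$t0)
  expect_gt(smp$u(cbind(5 * 10.24, 0))[3], 0.01 * peak)
})

test_that("sampler is linear in the applied force and axisymmetric", {
  sub <- elastic_substrate(1500, 0.45)
  s1 <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(8, sub, F_amp = 10), 1, 80)
  s2 <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(8, sub, F_amp = 20), 1, 80)
  pts <- cbind(c(0, 3, 11, -7), c(0, 4, -2, 1))
  expect_equal(s2$u(pts), 2 * s1$u(pts), tolerance = 1e-12)
  expect_equal(s2$t(pts), 2 * s1$t(pts), tolerance = 1e-12)
  ## mirrored sample points: equal u_z, opposite in-plane component
  d <- cbind(c(2.3, 5.1), c(1.1, -0.7))
  up <- s1$u(d); um <- s1$u(-d)
  expect_equal(up[, 3], um[, 3], tolerance = 1e-9)
  expect_equal(up[, 1:2], -um[, 1:2], tolerance = 1e-9)
})

test_that("zero load gives identically zero fields", {
  sub <- elastic_substrate(1500, 0.45)
  smp <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(8, sub, F_amp = 0), 1, 80)
  pts <- cbind(runif(5, -20, 20), runif(5, -20, 20))
  expect_true(all(smp$u(pts) == 0))
  expect_true(all(smp$t(pts) == 0))
  expect_equal(smp$peak_disp, 0)
})

test_that("sampler rejects invalid scenes and domains", {
  sub <- elastic_substrate(1500, 0.45)
  sc <- gaussian_traction_scene(8, sub, F_amp = 10)
  expect_error(boussinesq_gaussian_sampler(sc, 8 / 4, 80), "W/8")
  expect_error(boussinesq_gaussian_sampler(sc, 1, 5), "domain too small")
  expect_error(elastic_substrate(1500, 0.5), "nu")
  expect_error(gaussian_traction_scene(8, sub), "exactly one")
  expect_error(gaussian_traction_scene(8, sub, F_amp = 1, peak_disp = 1),
               "exactly one")
})

test_that("integrating the Gaussian z-traction recovers the prescribed force", {
  sub <- elastic_substrate(1500, 0.45)
  W <- 10.24
  smp <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(W, sub, F_amp = 40), W / 8, 60)
  g <- seq(-55, 55, by = W / 8)
  xy <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  tz <- smp$t(xy)[, 3]
  F_num <- sum(tz) * (W / 8)^2 / 1000          # Pa um^2 -> nN
  expect_lt(abs(F_num - 40) / 40, 0.01)
})

test_that("finite-thickness kernel limits to the half-space and to confined compression", {
  E <- 1500; nu <- 0.45; h <- 30
  cc <- eftfm:::layer_compliance(c(1e-4, 20 / h), E, nu, h)
  ## kh -> 0: confined compression h/(lambda + 2 mu)
  conf <- h * (1 + nu) * (1 - 2 * nu) / (E * (1 - nu))
  expect_equal(cc$Czz[1], conf, tolerance = 1e-3)
  ## kh large: half-space 2(1-nu^2)/(Ek)
  expect_equal(cc$Czz[2], 2 * (1 - nu^2) / (E * 20 / h), tolerance = 1e-6)
  ## deep-layer sampler approaches the half-space closed form
  subL <- elastic_substrate(E, nu, depth = 400)
  subH <- elastic_substrate(E, nu)
  scL <- gaussian_traction_scene(10.24, subL, F_amp = 40)
  scH <- gaussian_traction_scene(10.24, subH, F_amp = 40)
  smpL <- boussinesq_gaussian_sampler(scL, 10.24 / 8, 60)
  smpH <- boussinesq_gaussian_sampler(scH, 10.24 / 8, 60)
  pts <- cbind(c(0, 5, 10), 0)
  expect_equal(smpL$u(pts)[, 3], smpH$u(pts)[, 3], tolerance = 0.03)
  expect_equal(smpL$u(pts)[2:3, 1], smpH$u(pts)[2:3, 1], tolerance = 0.03)
})

test_that("layer-kernel sampler agrees with direct Hankel integration of the compliance", {
  E <- 1500; nu <- 0.45; h <- 30.3; W <- 10.24
  s <- W / (2 * sqrt(2 * log(2)))
  sub <- elastic_substrate(E, nu, depth = h)
  smp <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(W, sub, F_amp = 8), W / 16, 62)
  t0 <- 8 * 1000 / (2 * pi * s^2)
  kk <- seq(1e-6, 8 / s, length.out = 8000)
  Cz <- eftfm:::layer_compliance(kk, E, nu, h)$Czz
  uz_oracle <- function(r) vapply(r, function(ri) {
    f <- Cz * s^2 * t0 * exp(-kk^2 * s^2 / 2) * besselJ(kk * ri, 0) * kk
    sum((f[-1] + f[-length(f)]) / 2 * diff(kk))
  }, numeric(1))
  rs <- c(0, 3, 7, 12, 20)
  expect_equal(unname(smp$u(cbind(rs, 0))[, 3]), uz_oracle(rs),
               tolerance = 2e-3)
})

test_that("bead seeding is reproducible, respects exclusion, and reports infeasible packings", {
  spec <- bead_layer_spec(c(30, 30), density = 0.06, z_mean = 5,
                          z_sigma = 0.2, exclusion_radius = 1, seed = 11)
  b1 <- seed_beads(spec); b2 <- seed_beads(spec)
  expect_identical(b1, b2)
  D <- as.matrix(dist(cbind(b1$x, b1$y)))
  diag(D) <- Inf
  expect_gte(min(D), 1)
  ## count within 3 sigma of the Poisson expectation
  lam <- 0.06 * 900
  expect_lt(abs(nrow(b1) - lam), 3 * sqrt(lam) + 1)
  ## degenerate layer
  b3 <- seed_beads(bead_layer_spec(c(30, 30), 0.05, z_mean = 2, z_sigma = 0,
                                   seed = 2))
  expect_true(all(b3$z == 2))
  ## infeasible packing
  expect_error(
    seed_beads(bead_layer_spec(c(10, 10), 5, exclusion_radius = 3, seed = 1)),
    "packing failure")
})

test_that("rendering inserts templates exactly and superposes distant beads", {
  tmpl <- bead_template(half_size = c(4, 4, 3))
  sp <- tmpl$spacing
  ## one bead exactly at a voxel centre: bitwise template insertion
  b <- data.frame(x = 15 * sp[1], y = 17 * sp[2], z = 8 * sp[3])
  class(b) <- c("bead_set", "data.frame")
  v <- render_volume(b, tmpl, c(40, 40, 20), noise = noise_model(0, 0))
  sub <- v$data[(16 - 4):(16 + 4), (18 - 4):(18 + 4), (9 - 3):(9 + 3)]
  expect_identical(sub, tmpl$data)
  expect_equal(sum(v$data), sum(tmpl$data))
  ## two distant beads superpose
  b2 <- data.frame(x = c(10, 30) * sp[1], y = c(10, 30) * sp[2],
                   z = c(8, 12) * sp[3])
  class(b2) <- c("bead_set", "data.frame")
  v2 <- render_volume(b2, tmpl, c(40, 40, 20), noise = noise_model(0, 0))
  va <- render_volume(b2[1, ], tmpl, c(40, 40, 20), noise = noise_model(0, 0))
  vb <- render_volume(b2[2, ], tmpl, c(40, 40, 20), noise = noise_model(0, 0))
  expect_equal(v2$data, va$data + vb$data, tolerance = 1e-12)
  ## empty bead set: background + noise with a warning
  e <- b2[0, ]
  expect_warning(v0 <- render_volume(e, tmpl, c(20, 20, 10),
                                     noise = noise_model(0.01, 0.05)),
                 "empty bead set")
  expect_equal(mean(v0$data), 0.05, tolerance = 0.01)
})

test_that("noise realizations average to the noiseless render", {
  tmpl <- bead_template(half_size = c(4, 4, 3))
  b <- data.frame(x = 2.0, y = 2.1, z = 1.6)
  class(b) <- c("bead_set", "data.frame")
  clean <- render_volume(b, tmpl, c(26, 26, 12), noise = noise_model(0, 0.05))
  nm <- noise_model(gaussian_sigma = 0.02, background = 0.05)
  n_rep <- 40
  acc <- array(0, c(26, 26, 12))
  for (i in seq_len(n_rep))
    acc <- acc + render_volume(b, tmpl, c(26, 26, 12), noise = nm,
                               noise_seed = i)$data
  avg <- acc / n_rep
  ## voxelwise agreement within 3 sigma / sqrt(N) (away from the clip floor)
  interior <- clean$data > 0.06
  tol <- 3 * 0.02 / sqrt(n_rep)
  expect_lt(max(abs(avg[interior] - clean$data[interior])), 2 * tol)
})

test_that("deform_beads applies the analytic field and preserves identity", {
  sub <- elastic_substrate(1500, 0.45)
  sc0 <- gaussian_traction_scene(8, sub, F_amp = 0)
  smp0 <- boussinesq_gaussian_sampler(sc0, 1, 50)
  b <- seed_beads(bead_layer_spec(c(20, 20), 0.05, z_mean = 3, seed = 4))
  expect_identical(deform_beads(b, smp0), b)
  sc <- gaussian_traction_scene(10.24, sub, peak_disp = 0.32,
                                center = c(10, 10))
  smp <- boussinesq_gaussian_sampler(sc, 10.24 / 8, 55)
  ctr <- data.frame(x = 10, y = 10, z = 3)
  class(ctr) <- c("bead_set", "data.frame")
  moved <- deform_beads(ctr, smp)
  expect_equal(moved$z - 3, 0.32, tolerance = 1e-9)
  bd <- deform_beads(b, smp)
  expect_equal(nrow(bd), nrow(b))
  ## displacement magnitudes bounded by the peak
  expect_lte(max(sqrt((bd$x - b$x)^2 + (bd$y - b$y)^2 + (bd$z - b$z)^2)),
             0.32 + 1e-9)
})
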