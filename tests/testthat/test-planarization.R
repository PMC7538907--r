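scatter_field <- function(n = 200, seed = 5, f = function(x, y) 0 * x) {
  set.seed(seed)
  x <- runif(n, 0, 40); y <- runif(n, 0, 40)
  out <- data.frame(x = x, y = y, z = rnorm(n, 5, 0.1),
                    ux = 0, uy = 0, uz = f(x, y), score = 0)
  class(out) <- c("scattered_displacement_field", "data.frame")
  out
}

test_that("z-outlier rejection removes exactly the planted outlier", {
  f <- scatter_field(60)
  f$z <- 5
  f$z[13] <- 5 + 2        # 10+ sigma once the others get tiny jitter
  f$z[-13] <- 5 + rnorm(59, 0, 0.02)
  out <- reject_z_outliers(f, n_std = 3)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false((5 + 2) %in% out$z)
  ## perfectly coplanar: nothing removed for any positive n_std
  f2 <- scatter_field(30); f2$z <- 7
  expect_equal(attr(reject_z_outliers(f2, 0.5), "n_removed"), 0L)
  expect_error(reject_z_outliers(f2[1:5, ], 3), "at least 10")
})

test_that("z-outlier rejection removes a small normal-tail fraction at n_std = 3", {
  set.seed(6)
  removed <- vapply(1:30, function(i) {
    f <- scatter_field(300, seed = i)
    attr(reject_z_outliers(f, 3), "n_removed")
  }, numeric(1))
  ## 3-sigma two-sided tail: 0.27% expected; allow Monte-Carlo spread
  expect_lt(mean(removed) / 300, 0.012)
})

test_that("plane fitting is exact on noiseless planes and accurate under noise", {
  b <- data.frame(x = runif(50, 0, 30), y = runif(50, 0, 30))
  b$z <- 5
  p <- fit_plane(b)
  expect_equal(p$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(p$point[3]), 5, tolerance = 1e-12)
  ## tilted plane z = 0.1 x + 2: normal (-0.1, 0, 1)/|.|
  b2 <- b; b2$z <- 0.1 * b2$x + 2
  p2 <- fit_plane(b2)
  expect_equal(p2$normal, c(-0.1, 0, 1) / sqrt(1.01), tolerance = 1e-9)
  ## noisy plane: normal within 0.5 degrees
  set.seed(7)
  b3 <- data.frame(x = runif(1000, 0, 50), y = runif(1000, 0, 50))
  b3$z <- 0.05 * b3$x - 0.03 * b3$y + 4 + rnorm(1000, 0, 0.2)
  p3 <- fit_plane(b3)
  truth <- c(-0.05, 0.03, 1) / sqrt(1 + 0.05^2 + 0.03^2)
  ang <- acos(min(sum(p3$normal * truth), 1)) * 180 / pi
  expect_lt(ang, 0.5)
  ## collinear degenerate
  bc <- data.frame(x = 1:10, y = 2 * (1:10), z = rep(1, 10))
  expect_error(fit_plane(bc), "collinear")
})

test_that("affine displacement fields are reproduced exactly for any lambda", {
  f <- scatter_field(150, f = function(x, y) 0.01 * x + 0.02 * y)
  f$ux <- 0.005 * f$x - 0.001 * f$y + 0.3
  plane <- fit_plane(data.frame(x = f$x, y = f$y, z = 0))
  gs <- list(x = seq(-22, 22, length.out = 23),
             y = seq(-22, 22, length.out = 23))
  for (lam in c(1e-6, 1e-2, 1e2)) {
    g <- regularized_resample(f, plane, gs, lambda_xy = lam, lambda_z = lam)
    ## plane coords equal global x,y minus centroid here (normal = +z)
    gx <- outer(g$x + plane$point[1], rep(1, length(g$y)))
    gy <- outer(rep(1, length(g$x)), g$y + plane$point[2])
    expect_equal(g$uz, 0.01 * gx + 0.02 * gy, tolerance = 1e-6)
    expect_equal(g$ux, 0.005 * gx - 0.001 * gy + 0.3, tolerance = 1e-6)
  }
})

test_that("the penalty-dominated limit approaches the best-fit affine field", {
  set.seed(8)
  f <- scatter_field(300, f = function(x, y) 0.2 + 0 * x)
  f$uz <- f$uz + rnorm(300, 0, 0.05)
  plane <- fit_plane(data.frame(x = f$x, y = f$y, z = 0))
  gs <- list(x = seq(-21, 21, length.out = 20),
             y = seq(-21, 21, length.out = 20))
  g <- regularized_resample(f, plane, gs, lambda_z = 1e8)
  fit <- lm(uz ~ x + y, data = as.data.frame(f))
  gx <- outer(g$x + plane$point[1], rep(1, length(g$y)))
  gy <- outer(rep(1, length(g$x)), g$y + plane$point[2])
  pred <- coef(fit)[1] + coef(fit)[2] * gx + coef(fit)[3] * gy
  expect_equal(g$uz, unname(pred), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("regularized gridding reduces noise relative to the scattered data", {
  set.seed(9)
  sub <- elastic_substrate(1500, 0.45)
  smp <- boussinesq_gaussian_sampler(
    gaussian_traction_scene(10.24, sub, peak_disp = 0.32, center = c(20, 20)),
    10.24 / 8, 45)
  f <- scatter_field(250, seed = 9)
  u <- smp$u(cbind(f$x, f$y))
  sigma_n <- 0.1      # strongly noisy scattered data: the regime the
                      # curvature regularizer exists for
  f$ux <- u[, 1] + rnorm(250, 0, sigma_n)
  f$uy <- u[, 2] + rnorm(250, 0, sigma_n)
  f$uz <- u[, 3] + rnorm(250, 0, sigma_n)
  plane <- fit_plane(data.frame(x = f$x, y = f$y, z = 0))
  ## default grid spacing: about four mean bead spacings (the bead set
  ## above has ~1.3 um nearest-neighbour spacing)
  gs <- list(x = seq(-20, 20, length.out = 9),
             y = seq(-20, 20, length.out = 9))
  g <- regularized_resample(f, plane, gs)
  gx <- as.vector(outer(g$x + plane$point[1], rep(1, length(g$y))))
  gy <- as.vector(outer(rep(1, length(g$x)), g$y + plane$point[2]))
  ut <- smp$u(cbind(gx, gy))
  um <- cbind(as.vector(g$ux), as.vector(g$uy), as.vector(g$uz))
  ## score the data-supported region (the border ring is regularizer
  ## extrapolation, flagged separately in the report)
  ii <- rep(seq_along(g$x), times = length(g$y))
  jj <- rep(seq_along(g$y), each = length(g$x))
  interior <- ii > 1 & ii < length(g$x) & jj > 1 & jj < length(g$y)
  grid_rms <- sqrt(mean(rowSums((um - ut)[interior, ]^2)))
  raw_rms <- sqrt(3 * sigma_n^2)
  expect_lt(grid_rms, raw_rms)
  ## no overshoot blow-up: extrema within scattered extrema +- 5% of range
  rng <- diff(range(f$uz))
  expect_lt(max(g$uz[matrix(interior, length(g$x))]), max(f$uz) + 0.05 * rng)
  expect_gt(min(g$uz[matrix(interior, length(g$x))]), min(f$uz) - 0.05 * rng)
})
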