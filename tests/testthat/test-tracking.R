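test_that("radial symmetry is exact for a voxel-centred symmetric blob", {
  g <- seq(-5, 5)
  blob <- outer(outer(exp(-g^2 / 4), exp(-g^2 / 4)), exp(-g^2 / 4))
  ctr <- eftfm:::radial_symmetry_center(blob)
  expect_equal(ctr, c(6, 6, 6), tolerance = 1e-6)
})

test_that("subvoxel bead offsets are recovered within 0.05 voxel", {
  tmpl <- bead_template(half_size = c(6, 6, 8))
  sp <- tmpl$spacing
  offsets <- rbind(c(0.3, -0.2, 0.4), c(-0.45, 0.1, -0.3), c(0.25, 0.25, 0))
  for (i in seq_len(nrow(offsets))) {
    off <- offsets[i, ]
    b <- data.frame(x = (19 + off[1]) * sp[1], y = (19 + off[2]) * sp[2],
                    z = (13 + off[3]) * sp[3])
    class(b) <- c("bead_set", "data.frame")
    v <- render_volume(b, tmpl, c(40, 40, 28), noise = noise_model(0, 0))
    ## window sized to the rendered blob (sigma_z = 1.35 um = 4.5 slices)
    loc <- localize_beads(v, intensity_threshold = 0.3,
                          window_half_size = c(5, 5, 10))
    expect_equal(nrow(loc), 1L)
    err_vox <- c(loc$x - b$x, loc$y - b$y, loc$z - b$z) / sp
    expect_lt(max(abs(err_vox)), 0.05)
  }
})

test_that("localization on a dense noisy phantom stays below 0.1 in-plane voxel RMS", {
  tmpl <- bead_template()
  spec <- bead_layer_spec(c(25, 25), density = 0.0625, z_mean = 4.65,
                          z_sigma = 0.15, seed = 3)
  beads <- seed_beads(spec, origin = c(1.5, 1.5))
  v <- render_volume(beads, tmpl, c(180, 180, 32), noise = noise_model())
  loc <- localize_beads(v)
  P <- cbind(loc$x, loc$y, loc$z)
  err <- vapply(seq_len(nrow(beads)), function(i) {
    min(sqrt((P[, 1] - beads$x[i])^2 + (P[, 2] - beads$y[i])^2 +
               (P[, 3] - beads$z[i])^2))
  }, numeric(1))
  matched <- err < 0.4
  expect_gt(mean(matched), 0.95)
  err_xy <- vapply(which(matched), function(i) {
    j <- which.min((P[, 1] - beads$x[i])^2 + (P[, 2] - beads$y[i])^2 +
                     (P[, 3] - beads$z[i])^2)
    sqrt((P[j, 1] - beads$x[i])^2 + (P[j, 2] - beads$y[i])^2)
  }, numeric(1))
  expect_lt(sqrt(mean(err_xy^2)) / 0.16, 0.1)
})

test_that("feature vectors are translation invariant and match hand-computed offsets", {
  b <- data.frame(x = c(0, 1, 3, 0, 2), y = c(0, 0, 1, 2, 3),
                  z = c(0, 0.5, 0, 1, 0))
  f1 <- build_feature_vectors(b, k_neighbors = 3)
  b2 <- b; b2$x <- b$x + 7.3; b2$y <- b$y - 2.1; b2$z <- b$z + 0.9
  f2 <- build_feature_vectors(b2, k_neighbors = 3)
  expect_equal(f1, f2, tolerance = 1e-12)
  ## hand-computed descriptor of bead 1 at (0,0,0):
  ## neighbour distances: b2 1.118, b4 2.236, b5 3.606, b3 3.162 ->
  ## sorted k=3 neighbours are beads 2, 4, 3
  expect_equal(f1[1, ], c(1, 0, 0.5, 0, 2, 1, 3, 1, 0), tolerance = 1e-12)
  expect_error(build_feature_vectors(b, k_neighbors = 5), "more than")
})

test_that("an isolated far outlier has an oversized descriptor norm", {
  set.seed(1)
  b <- data.frame(x = runif(30, 0, 10), y = runif(30, 0, 10),
                  z = rnorm(30, 0, 0.2))
  b[31, ] <- c(50, 50, 0)
  f <- build_feature_vectors(b, 5)
  norms <- sqrt(rowSums(f^2))
  expect_gt(norms[31], 2 * median(norms))
})

test_that("identity tracking returns exact zeros at full match rate", {
  set.seed(2)
  b <- data.frame(x = runif(60, 0, 20), y = runif(60, 0, 20),
                  z = rnorm(60, 5, 0.2))
  class(b) <- c("bead_set", "data.frame")
  tr <- track(b, b)
  expect_equal(attr(tr, "match_rate"), 1)
  expect_true(all(tr$ux == 0 & tr$uy == 0 & tr$uz == 0))
})

test_that("rigid translations are tracked exactly and ordering does not matter", {
  set.seed(3)
  b <- data.frame(x = runif(80, 0, 25), y = runif(80, 0, 25),
                  z = rnorm(80, 5, 0.2))
  class(b) <- c("bead_set", "data.frame")
  d <- b; d$x <- d$x + 1.0
  tr <- track(b, d, max_disp = 5)
  expect_equal(attr(tr, "match_rate"), 1)
  expect_equal(unname(colMeans(cbind(tr$ux, tr$uy, tr$uz))), c(1, 0, 0),
               tolerance = 1e-9)
  ## permutation invariance of the linked set
  perm <- sample(nrow(d))
  tr2 <- track(b, d[perm, ], max_disp = 5)
  o1 <- order(tr$x, tr$y); o2 <- order(tr2$x, tr2$y)
  expect_equal(as.data.frame(tr)[o1, 1:6], as.data.frame(tr2)[o2, 1:6],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the normalized median test removes planted vector outliers", {
  set.seed(4)
  b <- data.frame(x = runif(70, 0, 20), y = runif(70, 0, 20),
                  z = rnorm(70, 5, 0.1))
  class(b) <- c("bead_set", "data.frame")
  d <- b; d$x <- d$x + 0.5
  d$x[5] <- d$x[5] + 3.0        # corrupt one link target
  tr <- track(b, d, max_disp = 8)
  ## the corrupted bead is either dropped or its link removed as an outlier
  bad <- which(abs(tr$ux - 0.5) > 0.5)
  expect_length(bad, 0)
})

test_that("tracking reports an informative failure when nothing links", {
  b <- data.frame(x = 1:12, y = rep(1, 12), z = rep(0, 12))
  class(b) <- c("bead_set", "data.frame")
  d <- b; d$x <- d$x + 500
  expect_error(track(b, d, max_disp = 2), "zero links")
})
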