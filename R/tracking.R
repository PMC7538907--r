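#' Localize bead centres at subvoxel precision
#'
#' Candidate beads are detected as 26-connected local intensity maxima
#' above a threshold, then each candidate is refined with the 3D
#' radial-symmetry method: within a local window, the centre is the point
#' minimizing the weighted squared distance to all voxel gradient lines
#' (weights `|grad I|^2`), which reduces to a 3x3 linear system and is
#' exact for any radially symmetric blob.  Duplicate detections within one
#' bead radius are merged.
#'
#' @param volume a deconvolved [volume_image()].
#' @param intensity_threshold detection threshold as a fraction of the
#'   bright-intensity scale (the 99.9th percentile of positive intensities
#'   after background-median subtraction).  A quantile rather than the
#'   maximum is used because deconvolution can concentrate a few beads
#'   into much brighter peaks than the typical bead.
#' @param bead_radius_voxels characteristic bead radius in voxels; the
#'   supported range 1.5-4.5 corresponds to bead diameters of 3-9 voxels.
#' @param window_half_size refinement window half-size in voxels, length 1
#'   or 3 (defaults to `ceiling(bead_radius_voxels) + 1` laterally and one
#'   voxel more axially, where bead images are usually more extended).
#' @return A `bead_set` data.frame with columns `x`, `y`, `z` (um) and
#'   `intensity` (peak intensity of the detected maximum).  Empty (with a
#'   warning) when nothing is detected.
#' @export
localize_beads <- function(volume, intensity_threshold = 0.3,
                           bead_radius_voxels = 2,
                           window_half_size = NULL) {
  stopifnot(inherits(volume, "volume_image"))
  if (bead_radius_voxels < 1.5 || bead_radius_voxels > 4.5)
    stop("bead_radius_voxels must lie in [1.5, 4.5] (bead diameter 3-9 voxels)")
  a <- volume$data
  bg <- stats::median(a)
  a <- pmax(a - bg, 0)
  pos <- a[a > 0]
  scale <- if (length(pos) > 0) stats::quantile(pos, 0.999) else 0
  thr <- max(intensity_threshold * scale,
             6 * stats::mad(pos))          # guard against pure-noise volumes
  pk <- find_local_maxima(a, thr)
  if (nrow(pk) == 0L) {
    warning("no bead candidates above threshold")
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      intensity = numeric(0))
    class(out) <- c("bead_set", "data.frame")
    return(out)
  }
  if (is.null(window_half_size)) {
    wxy <- ceiling(bead_radius_voxels) + 1
    window_half_size <- c(wxy, wxy, wxy + 1)
  }
  w <- as.integer(rep_len(window_half_size, 3L))
  d <- dim(a)
  centers <- matrix(NA_real_, nrow(pk), 3)
  inten <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    c0 <- pk[i, ]
    lo <- pmax(c0 - w, 1L); hi <- pmin(c0 + w, d)
    if (any(hi - lo < 2L)) next                      # window collapsed at edge
    win <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    ctr <- radial_symmetry_center(win)
    if (any(!is.finite(ctr))) next
    centers[i, ] <- lo - 1 + ctr                     # voxel coords, 1-based
    inten[i] <- a[c0[1], c0[2], c0[3]]
  }
  ok <- is.finite(centers[, 1])
  centers <- centers[ok, , drop = FALSE]
  inten <- inten[ok]
  ## merge duplicates within one bead radius (keep the brighter)
  if (nrow(centers) > 1L) {
    ord <- order(inten, decreasing = TRUE)
    centers <- centers[ord, , drop = FALSE]; inten <- inten[ord]
    keep <- rep(TRUE, nrow(centers))
    for (i in seq_len(nrow(centers))) {
      if (!keep[i]) next
      if (i < nrow(centers)) {
        j <- (i + 1):nrow(centers)
        d2 <- (centers[j, 1] - centers[i, 1])^2 +
          (centers[j, 2] - centers[i, 2])^2 +
          (centers[j, 3] - centers[i, 3])^2
        keep[j[d2 < bead_radius_voxels^2]] <- FALSE
      }
    }
    centers <- centers[keep, , drop = FALSE]; inten <- inten[keep]
  }
  phys <- vox_to_phys(volume, centers)
  out <- data.frame(x = phys[, 1], y = phys[, 2], z = phys[, 3],
                    intensity = inten)
  out <- out[order(out$x, out$y, out$z), ]
  rownames(out) <- NULL
  class(out) <- c("bead_set", "data.frame")
  out
}

## 3D radial-symmetry centre of an intensity window.
## Gradient lines through each interior voxel (central differences, in
## voxel units) nearly intersect at the centre of a symmetric blob; the
## least-squares intersection solves sum_i w_i (I - n n^T)(c - r_i) = 0.
radial_symmetry_center <- function(win) {
  d <- dim(win)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  gx <- (win[ix + 1, iy, iz] - win[ix - 1, iy, iz]) / 2
  gy <- (win[ix, iy + 1, iz] - win[ix, iy - 1, iz]) / 2
  gz <- (win[ix, iy, iz + 1] - win[ix, iy, iz - 1]) / 2
  g2 <- gx^2 + gy^2 + gz^2
  use <- g2 > (1e-12 * max(g2))
  if (sum(use) < 6) return(rep(NA_real_, 3))
  gi <- which_arr(dim(gx)) + 1             # interior voxel coords in window
  gx <- as.vector(gx)[use]; gy <- as.vector(gy)[use]; gz <- as.vector(gz)[use]
  g2 <- as.vector(g2)[use]
  r <- gi[use, , drop = FALSE]
  ## A = sum w (I - nn^T), b = A r; w = g2, n = g/|g| => w nn^T = gg^T
  sw <- sum(g2)
  A <- matrix(c(sw - sum(gx * gx), -sum(gx * gy), -sum(gx * gz),
                -sum(gx * gy), sw - sum(gy * gy), -sum(gy * gz),
                -sum(gx * gz), -sum(gy * gz), sw - sum(gz * gz)), 3, 3)
  b <- c(sum((g2 - gx * gx) * r[, 1] - gx * gy * r[, 2] - gx * gz * r[, 3]),
         sum(-gx * gy * r[, 1] + (g2 - gy * gy) * r[, 2] - gy * gz * r[, 3]),
         sum(-gx * gz * r[, 1] - gy * gz * r[, 2] + (g2 - gz * gz) * r[, 3]))
  ctr <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, 3))
  ctr
}

#' Topology feature vectors for bead matching
#'
#' Builds, for each bead, a translation-invariant descriptor of its local
#' neighbourhood: the relative offset vectors to its `k` nearest
#' neighbours, sorted by distance and flattened.  Beads in the reference
#' and deformed sets that correspond physically have nearly identical
#' descriptors provided the local deformation gradient is moderate.
#'
#' @param beads a `bead_set`.
#' @param k_neighbors neighbourhood size (default 8).
#' @return A numeric matrix with one row per bead and `3 k` columns.
#' @export
build_feature_vectors <- function(beads, k_neighbors = 8L) {
  n <- nrow(beads)
  k <- as.integer(k_neighbors)
  if (n <= k) stop(sprintf("need more than k = %d beads, got %d", k, n))
  P <- cbind(beads$x, beads$y, beads$z)
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  feats <- matrix(0, n, 3L * k)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    off <- P[nb, , drop = FALSE] - matrix(P[i, ], k, 3, byrow = TRUE)
    feats[i, ] <- as.vector(t(off))
  }
  feats
}

#' Track beads between reference and deformed sets
#'
#' Topology-based particle tracking: beads are linked by nearest
#' feature-vector match (sum of squared differences between distance-sorted
#' neighbour offsets) among candidates within `max_disp`, verified by
#' mutual-best-match, refined by an iterative-deformation scheme (after
#' each pass a locally smoothed estimate of the displacement field warps
#' the reference positions, shrinking the effective search distance), and
#' cleaned with a normalized-median outlier test against neighbouring
#' displacement vectors.  Matching ties are broken by smaller positional
#' distance and then by lower candidate index, so the result is
#' deterministic and independent of input ordering.
#'
#' @param ref,def `bead_set`s for the reference and deformed states.
#' @param k_neighbors feature-vector neighbourhood size.
#' @param max_disp maximum allowed displacement magnitude (um); defaults to
#'   10 median nearest-neighbour spacings of the reference set.
#' @param n_iterations iterative-deformation passes.
#' @param outlier_threshold normalized-median test threshold (2 is the
#'   field-standard value); `Inf` disables outlier removal.
#' @param outlier_neighbors neighbours used by the outlier test.
#' @param outlier_eps noise floor (um) of the normalized-median test.
#' @return A `scattered_displacement_field`: data.frame with the retained
#'   reference positions (`x`, `y`, `z`), displacements (`ux`, `uy`, `uz`),
#'   and per-link feature-match `score` (smaller is better), with
#'   attributes `match_rate` and `n_outliers_removed`.
#' @export
track <- function(ref, def, k_neighbors = 8L, max_disp = NULL,
                  n_iterations = 3L, outlier_threshold = 2,
                  outlier_neighbors = 8L, outlier_eps = 0.05) {
  if (nrow(ref) == 0L || nrow(def) == 0L)
    stop("both bead sets must be non-empty")
  Pr <- cbind(ref$x, ref$y, ref$z)
  Pd <- cbind(def$x, def$y, def$z)
  k <- min(as.integer(k_neighbors), nrow(ref) - 1L, nrow(def) - 1L)
  if (k < 1L) stop("too few beads to build feature vectors")
  if (is.null(max_disp)) {
    nn <- apply(as.matrix(stats::dist(Pr)) + diag(Inf, nrow(Pr)), 1, min)
    max_disp <- 10 * stats::median(nn)
  }
  Fr <- build_feature_vectors(as.data.frame(list(x = Pr[, 1], y = Pr[, 2],
                                                 z = Pr[, 3])), k)
  Fd <- build_feature_vectors(as.data.frame(list(x = Pd[, 1], y = Pd[, 2],
                                                 z = Pd[, 3])), k)
  warped <- Pr
  match <- rep(NA_integer_, nrow(Pr))
  score <- rep(NA_real_, nrow(Pr))
  for (pass in seq_len(max(1L, as.integer(n_iterations)))) {
    search <- if (pass == 1L) max_disp else max(max_disp / (2^(pass - 1)), 1)
    res <- link_features(warped, Pd, Fr, Fd, search)
    match <- res$match; score <- res$score
    ok <- !is.na(match)
    if (!any(ok)) break
    ## smooth the current field (neighbour moving average) and warp
    u_est <- matrix(NA_real_, nrow(Pr), 3)
    u_est[ok, ] <- Pd[match[ok], , drop = FALSE] - Pr[ok, , drop = FALSE]
    u_smooth <- neighbor_average(Pr, u_est, k = max(k, 4L))
    warped <- Pr + u_smooth
  }
  ok <- which(!is.na(match))
  if (length(ok) == 0L)
    stop(sprintf(
      "zero links survived (0/%d matched): check max_disp and bead density",
      nrow(Pr)))
  u <- Pd[match[ok], , drop = FALSE] - Pr[ok, , drop = FALSE]
  ## enforce the displacement bound on the final links
  keep <- sqrt(rowSums(u^2)) <= max_disp + 1e-9
  ok <- ok[keep]; u <- u[keep, , drop = FALSE]
  match_rate <- length(ok) / nrow(ref)   # linked fraction before cleaning
  ## normalized median test
  n_out <- 0L
  if (is.finite(outlier_threshold) && length(ok) > outlier_neighbors + 1) {
    good <- normalized_median_filter(Pr[ok, , drop = FALSE], u,
                                     outlier_threshold, outlier_neighbors,
                                     outlier_eps)
    n_out <- sum(!good)
    ok <- ok[good]; u <- u[good, , drop = FALSE]
  }
  out <- data.frame(x = Pr[ok, 1], y = Pr[ok, 2], z = Pr[ok, 3],
                    ux = u[, 1], uy = u[, 2], uz = u[, 3],
                    score = score[ok])
  attr(out, "match_rate") <- match_rate
  attr(out, "n_outliers_removed") <- n_out
  class(out) <- c("scattered_displacement_field", "data.frame")
  out
}

## feature matching among positional candidates; mutual best match kept
link_features <- function(Pr, Pd, Fr, Fd, search) {
  n <- nrow(Pr); m <- nrow(Pd)
  best <- rep(NA_integer_, n)
  best_cost <- rep(Inf, n)
  posd2 <- rep(Inf, n)
  for (i in seq_len(n)) {
    d2 <- (Pd[, 1] - Pr[i, 1])^2 + (Pd[, 2] - Pr[i, 2])^2 +
      (Pd[, 3] - Pr[i, 3])^2
    cand <- which(d2 <= search^2)
    if (length(cand) == 0L) next
    cost <- colSums((t(Fd[cand, , drop = FALSE]) - Fr[i, ])^2)
    ## deterministic tie-breaks: feature cost, positional distance, index
    o <- order(cost, d2[cand], cand)[1]
    best[i] <- cand[o]
    best_cost[i] <- cost[o]
    posd2[i] <- d2[cand[o]]
  }
  ## mutual best: each deformed bead may be claimed by one reference bead
  match <- rep(NA_integer_, n)
  claimed <- !is.na(best)
  if (any(claimed)) {
    for (j in unique(best[claimed])) {
      claimants <- which(best == j)
      o <- order(best_cost[claimants], posd2[claimants], claimants)[1]
      match[claimants[o]] <- j
    }
  }
  list(match = match, score = best_cost)
}

## moving-average smoothing of a (partially observed) vector field over
## k nearest neighbours; missing rows are filled from their neighbours
neighbor_average <- function(P, U, k) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(min(k, n - 1L))]
    vals <- rbind(U[i, ], U[nb, , drop = FALSE])
    vals <- vals[stats::complete.cases(vals), , drop = FALSE]
    if (nrow(vals) > 0) out[i, ] <- colMeans(vals)
  }
  out
}

## universal (normalized median) outlier test on a vector field
normalized_median_filter <- function(P, U, threshold, k, eps) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  good <- rep(TRUE, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(min(k, n - 1L))]
    r <- 0
    for (c in 1:3) {
      med <- stats::median(U[nb, c])
      resid <- stats::median(abs(U[nb, c] - med))
      r <- max(r, abs(U[i, c] - med) / (resid + eps))
    }
    if (r > threshold) good[i] <- FALSE
  }
  good
}
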