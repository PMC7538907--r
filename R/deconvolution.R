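#' Extract an empirical point spread function from an isolated bead
#'
#' Under the assumption that a sub-resolution microbead is a point-like
#' light source, its image is the transfer function of the optical system.
#' A region of interest around an isolated bead is extracted, the local
#' background (median of the ROI border voxels) subtracted and clipped at
#' zero, the blob recentred on the patch grid, and the result normalized to
#' unit sum.
#'
#' @param volume a [volume_image()].
#' @param center_hint integer voxel coordinates `(i, j, k)` near the bead.
#' @param roi_half_size integer half-size of the ROI in voxels
#'   `(hx, hy, hz)`; the ROI must lie fully inside the volume and contain
#'   exactly one bead.
#' @return An object of class `point_spread_function`: a list with the
#'   normalized `data` array (sums to 1) and the voxel `spacing`.
#' @export
extract_psf <- function(volume, center_hint, roi_half_size = c(8, 8, 6)) {
  stopifnot(inherits(volume, "volume_image"))
  ch <- as.integer(round(center_hint))
  hs <- as.integer(roi_half_size)
  d <- dim(volume$data)
  lo <- ch - hs; hi <- ch + hs
  if (any(lo < 1L) || any(hi > d))
    stop("ROI clipped by the volume edge; choose a bead farther from the border")
  roi <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ## background = median of the 6 border faces
  rd <- dim(roi)
  border <- c(roi[c(1, rd[1]), , ], roi[, c(1, rd[2]), ], roi[, , c(1, rd[3])])
  bg <- stats::median(border)
  roi <- pmax(roi - bg, 0)
  if (max(roi) <= 0) stop("no peak in ROI: pure background")
  ## isolation check: count well-separated local maxima above 30% of peak
  pk <- find_local_maxima(roi, threshold = 0.3 * max(roi))
  if (nrow(pk) > 1L) {
    sep <- stats::dist(sweep(pk, 2, c(1, 1, 1), "*"))
    if (any(sep > 2)) {
      stop("multiple beads in ROI: the PSF must come from an isolated microbead")
    }
  }
  if (nrow(pk) == 0L) stop("no peak in ROI: pure background")
  ## recentre on the centre of mass (integer roll keeps the sample exact)
  com <- colSums(which_arr(rd) * as.vector(roi)) / sum(roi)
  ctr <- (rd + 1) / 2
  shift <- round(ctr - com)
  roi <- int_roll(roi, shift)
  psf <- roi / sum(roi)
  structure(list(data = psf, spacing = volume$spacing),
            class = "point_spread_function")
}

#' @export
print.point_spread_function <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<point_spread_function> %d x %d x %d voxels, sum = %.6f\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Richardson-Lucy deconvolution of a volume image
#'
#' Classic multiplicative-update maximum-likelihood (Poisson) deconvolution
#' with the measured PSF.  The volume-wide median background is subtracted
#' (clipped at zero) before iterating, which stabilizes the updates against
#' the additive fluorescence offset; edges are handled by reflective
#' padding; the mirrored PSF is used for the correction step as the
#' algorithm requires.  Iterations stop early once the relative update norm
#' falls below `tol`.
#'
#' @param volume a [volume_image()].
#' @param psf a [extract_psf()] result (or any unit-sum
#'   `point_spread_function`).
#' @param iterations maximum iteration count (`>= 1`); 10 is a typical
#'   choice for bead images.
#' @param tol early-stopping threshold on the relative update norm.
#' @param subtract_background subtract the volume median before iterating.
#' @return The deconvolved [volume_image()] (same shape and spacing).
#' @export
lucy_richardson <- function(volume, psf, iterations = 10L, tol = 1e-4,
                            subtract_background = TRUE) {
  stopifnot(inherits(volume, "volume_image"),
            inherits(psf, "point_spread_function"))
  if (iterations < 1L) stop("'iterations' must be >= 1")
  if (abs(sum(psf$data) - 1) > 1e-6) stop("PSF must be normalized to unit sum")
  d <- dim(volume$data)
  kd <- dim(psf$data)
  if (any(kd > d)) stop("PSF larger than the volume")
  img <- volume$data
  if (subtract_background) img <- pmax(img - stats::median(img), 0)
  ## reflective pad by the PSF half-size, iterate on the padded array
  ph <- (kd - 1L) %/% 2L
  padded <- reflect_pad(img, ph)
  pd <- dim(padded)
  K <- array(0, pd)
  K[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- psf$data
  K <- int_roll(K, -ph)                      # centre kernel at (1,1,1)
  Kf <- stats::fft(K)
  Kcf <- Conj(Kf)                            # transform of the mirrored PSF
  conv <- function(Xf_times) Re(stats::fft(Xf_times, inverse = TRUE)) / prod(pd)
  est <- pmax(padded, 1e-12)
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    blur <- conv(stats::fft(est) * Kf)
    ratio <- padded / pmax(blur, eps)
    corr <- conv(stats::fft(ratio) * Kcf)
    new_est <- pmax(est * corr, 0)
    delta <- sqrt(sum((new_est - est)^2)) / max(sqrt(sum(est^2)), eps)
    est <- new_est
    if (delta < tol) break
  }
  out <- est[ph[1] + seq_len(d[1]), ph[2] + seq_len(d[2]),
             ph[3] + seq_len(d[3]), drop = FALSE]
  volume_image(pmax(out, 0), volume$spacing, volume$origin)
}

## internal helpers --------------------------------------------------------

## integer circular shift of a 3D array
int_roll <- function(a, shift) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    s <- ((shift[ax]) %% d[ax])
    if (s == 0) seq_len(d[ax]) else c((d[ax] - s + 1):d[ax], 1:(d[ax] - s))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## reflective (mirror) padding of a 3D array by half-sizes ph
reflect_pad <- function(a, ph) {
  d <- dim(a)
  ix <- c(rev(seq_len(min(ph[1], d[1]))), seq_len(d[1]),
          d[1] + 1 - seq_len(min(ph[1], d[1])))
  iy <- c(rev(seq_len(min(ph[2], d[2]))), seq_len(d[2]),
          d[2] + 1 - seq_len(min(ph[2], d[2])))
  iz <- c(rev(seq_len(min(ph[3], d[3]))), seq_len(d[3]),
          d[3] + 1 - seq_len(min(ph[3], d[3])))
  a[ix, iy, iz, drop = FALSE]
}

## integer voxel coordinates (n x 3) of all array entries, column-major
which_arr <- function(d) {
  cbind(rep_len(seq_len(d[1]), prod(d)),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

## local maxima (26-connected) above a threshold; returns n x 3 voxel coords
find_local_maxima <- function(a, threshold) {
  d <- dim(a)
  if (any(d < 3L)) return(matrix(integer(0), 0, 3))
  core <- a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
  is_max <- core > threshold
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- a[(2 + dx):(d[1] - 1 + dx), (2 + dy):(d[2] - 1 + dy),
            (2 + dz):(d[3] - 1 + dz), drop = FALSE]
    is_max <- is_max & (core >= nb)
  }
  w <- which(is_max, arr.ind = TRUE)
  if (length(w) == 0L) return(matrix(integer(0), 0, 3))
  w <- matrix(w, ncol = 3)
  w + 1L                                   # account for the trimmed border
}

## full-width half-maximum (in samples) of a 1D profile about its peak
profile_fwhm <- function(p) {
  pk <- which.max(p)
  half <- p[pk] / 2
  left <- pk
  while (left > 1 && p[left - 1] > half) left <- left - 1
  right <- pk
  n <- length(p)
  while (right < n && p[right + 1] > half) right <- right + 1
  xl <- if (left > 1) {
    left - (p[left] - half) / (p[left] - p[left - 1])
  } else 1
  xr <- if (right < n) {
    right + (p[right] - half) / (p[right] - p[right + 1])
  } else n
  xr - xl
}

#' Measure the bead z-FWHM of a volume about its brightest voxel
#'
#' Convenience metric used to quantify the axial compaction achieved by
#' deconvolution (the z-spread of an epifluorescence bead image shrinks
#' markedly after Richardson-Lucy restoration).
#'
#' @param volume a [volume_image()].
#' @return FWHM of the axial intensity profile through the global maximum,
#'   in voxels.
#' @export
bead_z_fwhm <- function(volume) {
  stopifnot(inherits(volume, "volume_image"))
  a <- volume$data
  w <- arrayInd(which.max(a), dim(a))
  profile_fwhm(a[w[1], w[2], ])
}
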