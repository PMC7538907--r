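#' Volumetric intensity image with physical voxel spacing
#'
#' A `volume_image` is the carrier for raw, deconvolved and synthetic image
#' stacks: a 3D array of non-negative intensities together with the physical
#' voxel spacing and the physical position of the first voxel centre.  The
#' array is indexed `[ix, iy, iz]`; the physical coordinate of voxel
#' `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing` (micrometres).
#'
#' @param data 3D numeric array of intensities (all values `>= 0`).
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in um;
#'   all components `> 0`.
#' @param origin numeric length-3, physical position (um) of voxel
#'   `(1, 1, 1)`.  Defaults to the coordinate origin.
#' @return An object of class `volume_image`.
#' @examples
#' v <- volume_image(array(0, c(8, 8, 4)), spacing = c(0.16, 0.16, 0.3))
#' dim(v$data)
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (um per voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (um)")
  if (any(data < 0)) stop("volume intensities must be non-negative")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) um, intensity range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical extent of a volume image
#'
#' @param volume a [volume_image()].
#' @return Numeric length-3: the physical size (um) spanned by the voxel
#'   grid along x, y, z (`dim * spacing`).
#' @export
volume_extent <- function(volume) {
  stopifnot(inherits(volume, "volume_image"))
  dim(volume$data) * volume$spacing
}

#' Crop a sub-volume while keeping physical coordinates consistent
#'
#' Extracts the voxel box `[x0:x1, y0:y1, z0:z1]` and updates the origin so
#' that any physical position (for example a localized bead centre) is
#' unchanged by the crop.
#'
#' @param volume a [volume_image()].
#' @param box integer vector `c(x0, x1, y0, y1, z0, z1)` of 1-based voxel
#'   bounds, inclusive, inside the stack.
#' @return A [volume_image()] holding the sub-volume.
#' @export
crop_volume <- function(volume, box) {
  stopifnot(inherits(volume, "volume_image"))
  box <- as.integer(box)
  if (length(box) != 6L) stop("'box' must be c(x0, x1, y0, y1, z0, z1)")
  d <- dim(volume$data)
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  if (any(lo < 1L) || any(hi > d) || any(hi < lo))
    stop("crop box out of bounds for a ", paste(d, collapse = "x"), " volume")
  sub <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  volume_image(sub, volume$spacing,
               origin = volume$origin + (lo - 1L) * volume$spacing)
}

#' Read a multi-page TIFF stack as a volume image
#'
#' Pages are interpreted as z-slices; within a page, TIFF rows map to y and
#' columns to x, so the returned array is indexed `[x, y, z]`.
#'
#' @param path path to a multi-page grayscale TIFF (8 or 16 bit, or float).
#' @param spacing voxel spacing `(dx, dy, dz)` in um.
#' @param origin physical position of the first voxel (um).
#' @return A [volume_image()] with intensities in `[0, 1]` as returned by
#'   [tiff::readTIFF()].
#' @export
read_volume_tiff <- function(path, spacing, origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  p1 <- pages[[1]]
  if (length(dim(p1)) == 3L) {           # collapse RGB written by other tools
    pages <- lapply(pages, function(p) p[, , 1])
    p1 <- pages[[1]]
  }
  arr <- array(0, c(ncol(p1), nrow(p1), nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  volume_image(arr, spacing, origin)
}

#' Write a volume image as a multi-page 16-bit TIFF stack
#'
#' Intensities are clipped to `[0, 1]` before writing (the rendering and
#' deconvolution routines keep data in this range).
#'
#' @param volume a [volume_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  a <- pmin(pmax(volume$data, 0), 1)
  pages <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

## internal: voxel <-> physical coordinate helpers -------------------------

vox_to_phys <- function(volume, ijk) {
  sweep(sweep(ijk - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

phys_to_vox <- function(volume, xyz) {
  sweep(sweep(xyz, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
}

## internal: run code with a private RNG stream ----------------------------

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
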