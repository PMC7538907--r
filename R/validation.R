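#' Mean field-reconstruction uncertainty
#'
#' The uncertainty metric used throughout the synthetic validation:
#' `|Uncertainty| = sqrt(sum_n (chi_measured - chi_imposed)^2) / N`, the
#' square root of the total squared componentwise error divided by the
#' number of measurement points.  Note that this printed form divides by
#' `N` (not `sqrt(N)`): for a uniform pointwise error `e` it equals
#' `e / sqrt(N)` and therefore shrinks with the number of measurement
#' points.  The conventional RMS error (`sqrt(mean squared error)`) is
#' reported alongside for interpretability, together with the pointwise
#' standard error (sd of the pointwise error magnitudes / sqrt(N)).
#'
#' @param measured,imposed n x c matrices (or vectors) of field samples at
#'   identical measurement points.
#' @param field optional label (`"displacement"`, `"traction"`, ...).
#' @param sweep_value optional sweep parameter value (W or F) to attach.
#' @return An `uncertainty_report`: list with `uncertainty` (the metric
#'   above), `rms`, `std_error`, `N`, `field`, `sweep_value`.
#' @examples
#' uncertainty(rbind(c(1, 0, 0), c(0, 1, 0)), matrix(0, 2, 3))  # 0.7071
#' @export
uncertainty <- function(measured, imposed, field = "displacement",
                        sweep_value = NA_real_) {
  measured <- as.matrix(measured); imposed <- as.matrix(imposed)
  if (!all(dim(measured) == dim(imposed)))
    stop("measured and imposed fields must have matching dimensions")
  N <- nrow(measured)
  if (N == 0L) stop("empty field")
  err <- measured - imposed
  total_sq <- sum(err^2)
  mag <- sqrt(rowSums(err^2))
  structure(list(uncertainty = sqrt(total_sq) / N,
                 rms = sqrt(total_sq / N),
                 std_error = stats::sd(mag) / sqrt(N),
                 N = N, field = field, sweep_value = sweep_value),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> %s: |Uncertainty| = %.4g (RMS %.4g, SE %.4g, N = %d)\n",
              x$field, x$uncertainty, x$rms, x$std_error, x$N))
  invisible(x)
}

#' Signal-to-noise ratio of a reconstructed field
#'
#' Ratio of the peak signal magnitude to the mean uncertainty.  (The
#' quoted reference values of roughly 300 for displacement and 100 for
#' traction are on this signal-over-uncertainty orientation.)
#'
#' @param signal peak signal magnitude (scalar), or an n x c matrix whose
#'   peak row magnitude is used.
#' @param uncert an [uncertainty()] report (or a bare uncertainty value).
#' @return The SNR (dimensionless); `Inf` when the uncertainty is zero.
#' @export
snr <- function(signal, uncert) {
  peak <- if (is.matrix(signal)) max(sqrt(rowSums(signal^2)))
  else as.numeric(signal)
  u <- if (inherits(uncert, "uncertainty_report")) uncert$uncertainty
  else as.numeric(uncert)
  if (!is.finite(peak) || peak <= 0) stop("zero or invalid peak signal")
  if (u == 0) {
    warning("zero uncertainty: SNR overflows")
    return(Inf)
  }
  peak / u
}

#' Score a pipeline result against the synthetic ground truth
#'
#' Computes, at the top-surface grid nodes, the displacement and traction
#' uncertainty reports, the corresponding SNRs, and the force balance
#' between the integrated surface traction and the imposed force.
#'
#' @param case a [synthesize_case()].
#' @param result a [run_tfm()] result for that case.
#' @return List with `u_report`, `t_report`, `snr_displacement`,
#'   `snr_traction`, `force` (integrated, nN), `force_imposed` (nN) and
#'   `force_error` (relative).
#' @export
case_metrics <- function(case, result) {
  tr <- case_truth(case, result)
  ur <- uncertainty(tr$u_meas, tr$u_true, field = "displacement",
                    sweep_value = case$scene$W)
  tre <- uncertainty(tr$t_meas, tr$t_true, field = "traction",
                     sweep_value = case$scene$W)
  fz <- integrate_traction(result$traction)[["Fz"]]
  Fimp <- case$sampler$F_amp
  list(u_report = ur, t_report = tre,
       snr_displacement = snr(tr$u_meas, ur),
       snr_traction = snr(tr$t_meas, tre),
       force = fz, force_imposed = Fimp,
       force_error = if (Fimp != 0) abs(fz - Fimp) / Fimp else abs(fz))
}

#' Synthetic spatial-frequency / amplitude sweep
#'
#' Runs the full pipeline on freshly generated synthetic cases over a
#' sweep of Gaussian widths `W` (at fixed peak displacement) or force
#' amplitudes `F` (at fixed `W`), mirroring the frequency and amplitude
#' validation sweeps, and reports the uncertainty of the tracked (TPT)
#' displacements, the planarized/FE displacements, and the tractions at
#' each sweep point.  A failed sweep point is recorded and the sweep
#' continues.
#'
#' @param W_values Gaussian widths to sweep (um), or `NULL`.
#' @param F_values force amplitudes to sweep (nN), or `NULL` (exactly one
#'   of the two must be given).
#' @param peak_disp fixed peak displacement for the W sweep (um).
#' @param W fixed width for the F sweep (um).
#' @param seed base RNG seed (each sweep point uses `seed + index`).
#' @param case_args extra arguments passed to [synthesize_case()]
#'   (e.g. a reduced `volume_shape`).
#' @param opts a [tfm_options()].
#' @return A data.frame with one row per sweep point: the sweep value,
#'   uncertainties (TPT displacement, gridded displacement, traction),
#'   SNRs, force balance, and an `error` column for failed points.
#' @export
run_sweep <- function(W_values = NULL, F_values = NULL, peak_disp = 0.32,
                      W = 10.24, seed = 1L, case_args = list(),
                      opts = tfm_options()) {
  if (is.null(W_values) == is.null(F_values))
    stop("give exactly one of W_values or F_values")
  vals <- if (!is.null(W_values)) W_values else F_values
  rows <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    args <- c(list(seed = seed + i - 1L), case_args)
    if (!is.null(W_values)) {
      args$W <- vals[i]; args$peak_disp <- peak_disp
    } else {
      args$W <- W; args$F_amp <- vals[i]; args$peak_disp <- NULL
    }
    row <- data.frame(sweep = vals[i], tpt_uncertainty = NA_real_,
                      u_uncertainty = NA_real_, t_uncertainty = NA_real_,
                      snr_displacement = NA_real_, snr_traction = NA_real_,
                      force = NA_real_, force_imposed = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      case <- do.call(synthesize_case, args)
      result <- run_tfm(case$ref, case$def, opts)
      m <- case_metrics(case, result)
      ## TPT-level uncertainty at the tracked bead positions
      u_true_b <- case$sampler$u(cbind(result$tracked$x, result$tracked$y))
      tpt <- uncertainty(cbind(result$tracked$ux, result$tracked$uy,
                               result$tracked$uz), u_true_b,
                         field = "tpt displacement")
      row$tpt_uncertainty <- tpt$uncertainty
      row$u_uncertainty <- m$u_report$uncertainty
      row$t_uncertainty <- m$t_report$uncertainty
      row$snr_displacement <- m$snr_displacement
      row$snr_traction <- m$snr_traction
      row$force <- m$force
      row$force_imposed <- m$force_imposed
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}

#' Synthetic rigid-body displacement suite
#'
#' Emulates the stage-translation accuracy experiment: for each setpoint
#' and axis a bead layer is rendered, rigidly translated by the setpoint,
#' re-rendered with independent noise, and tracked; the measured mean
#' displacement is regressed against the applied displacement per axis.
#' (Deconvolution is unnecessary here: the rendered beads already satisfy
#' the tracker's size requirement, and the suite isolates localization
#' and tracking accuracy.)
#'
#' @param translations stage setpoints (um), e.g. `c(0, 1, 2, 3, 5, 10, 15)`.
#' @param axes subset of `c("x", "y", "z")`.
#' @param seed base RNG seed.
#' @param volume_shape stack size used for the phantoms; the z extent is
#'   enlarged automatically for z translations.
#' @param spacing voxel spacing (um).
#' @param density bead density (beads/um^2).
#' @param noise a [noise_model()].
#' @param window_half_size localization window (voxels); the default is
#'   sized to the un-deconvolved rendered bead, whose axial spread is
#'   much larger than after deconvolution.
#' @return List with `measurements` (data.frame: axis, applied, measured
#'   mean and sd per component) and `slopes` (per-axis regression slope of
#'   measured vs applied over the nonzero setpoints).
#' @export
rigid_body_suite <- function(translations = c(0, 1, 2, 3, 5, 10, 15),
                             axes = c("x", "y", "z"), seed = 1L,
                             volume_shape = c(256L, 256L, 32L),
                             spacing = c(0.16, 0.16, 0.3),
                             density = 0.0625, noise = noise_model(),
                             window_half_size = c(4L, 4L, 10L)) {
  tmpl <- bead_template(spacing = spacing)
  tz_half <- (dim(tmpl$data)[3] - 1L) %/% 2L
  rows <- list()
  ridx <- 0L
  for (axis in axes) {
    ai <- match(axis, c("x", "y", "z"))
    shape <- as.integer(volume_shape)
    if (axis == "z") {
      need <- ceiling(max(translations) / spacing[3]) + shape[3]
      shape[3] <- max(shape[3], need)
    }
    extent <- (shape - 1L) * spacing
    margin <- 8 * spacing[1]
    z0 <- if (axis == "z") (tz_half + 2) * spacing[3] else extent[3] / 2
    spec <- bead_layer_spec(
      extent = extent[1:2] - c(margin, margin) -
        if (axis %in% c("x", "y")) max(translations) else 0,
      density = density, z_mean = z0, z_sigma = 0.15,
      exclusion_radius = 1.0, seed = seed + ai * 1000L)
    beads <- seed_beads(spec, origin = c(margin / 2, margin / 2))
    ref <- render_volume(beads, tmpl, shape, spacing, noise,
                         noise_seed = seed + ai * 2000L)
    ref_loc <- localize_beads(ref, window_half_size = window_half_size)
    for (d in translations) {
      ridx <- ridx + 1L
      shifted <- beads
      shifted[[axis]] <- shifted[[axis]] + d
      defv <- render_volume(shifted, tmpl, shape, spacing, noise,
                            noise_seed = seed + ai * 2000L + ridx)
      def_loc <- localize_beads(defv, window_half_size = window_half_size)
      field <- track(ref_loc, def_loc,
                     max_disp = max(2, 1.5 * max(translations)))
      u <- cbind(field$ux, field$uy, field$uz)
      rows[[ridx]] <- data.frame(
        axis = axis, applied = d,
        mean_ux = mean(u[, 1]), mean_uy = mean(u[, 2]),
        mean_uz = mean(u[, 3]),
        sd_along = stats::sd(u[, ai]),
        measured = mean(u[, ai]),
        n_links = nrow(field))
    }
  }
  meas <- do.call(rbind, rows)
  slopes <- vapply(axes, function(axis) {
    m <- meas[meas$axis == axis & meas$applied > 0, ]
    if (nrow(m) < 2) return(NA_real_)
    stats::coef(stats::lm(measured ~ applied, data = m))[["applied"]]
  }, numeric(1))
  list(measurements = meas, slopes = slopes)
}
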