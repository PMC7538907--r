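#' Default options for the end-to-end reconstruction
#'
#' Collects every tunable parameter of the workflow in one structure; any
#' entry can be overridden by name.  Units: um for lengths, Pa for moduli.
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `tfm_options`.
#' @export
tfm_options <- function(...) {
  opts <- list(
    material = list(E = 1500, nu = 0.45),   # typical soft polyacrylamide
    depth = 30.3,                           # substrate thickness (um)
    deconvolve = TRUE,
    decon_iterations = 10L,
    psf_roi_half_size = c(8L, 8L, 10L),
    intensity_threshold = 0.3,
    bead_radius_voxels = 2,
    k_neighbors = 8L,
    max_disp = NULL,                        # default: 10 bead spacings
    track_iterations = 3L,
    outlier_threshold = 2,
    n_std = 3,
    lambda_xy = 1e-3,
    lambda_z = 1e-3,
    mesh = mesh_config(),
    formulation = "neohookean",
    rtol = 1e-8,
    ## computational domain: lateral extent from the bead bounding box
    ## ("beads") or the full imaged volume ("volume")
    domain = "beads",
    ## lateral faces: the standard scheme ("default": left face u_x = 0,
    ## back face u_y = 0, right/front free) or frictionless walls on all
    ## four lateral faces ("mirror"), exact for a centred symmetric scene
    ## treated as one unit cell of a periodic array
    lateral_bc = "default")
  ov <- list(...)
  if (length(ov) > 0) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(ov), names(opts))
    if (length(unknown) > 0)
      stop("unknown option(s): ", paste(unknown, collapse = ", "))
    opts[names(ov)] <- ov
  }
  class(opts) <- "tfm_options"
  opts
}

#' Generate a complete synthetic validation case
#'
#' Builds the analytic Gaussian-indentation scene on the configured
#' substrate, seeds a random near-planar bead layer at experiment-like
#' density, renders the reference stack, displaces the beads by the
#' analytic surface field and renders the deformed stack, both corrupted
#' with the noise model.  The returned object carries the ground-truth
#' sampler and per-bead correspondences, so every pipeline stage can be
#' scored against truth.
#'
#' @param W Gaussian traction full-width half-magnitude (um).
#' @param peak_disp peak surface displacement (um); give either this or
#'   `F_amp`.
#' @param F_amp total force (nN).
#' @param E,nu substrate elastic constants.
#' @param depth substrate thickness (um); the analytic solution uses the
#'   bonded-layer Green's function of this thickness so that truth and the
#'   fixed-bottom computational domain describe the same mechanics.
#' @param volume_shape stack size in voxels `(nx, ny, nz)`.
#' @param spacing voxel spacing (um).
#' @param density bead density (beads/um^2).
#' @param z_sigma bead-layer z spread (um).
#' @param noise a [noise_model()].
#' @param seed integer seed controlling seeding and both noise
#'   realizations.
#' @return A list of class `tfm_case`: `ref`, `def` (volume images),
#'   `sampler`, `beads_ref`, `beads_def`, `template`, and the scene
#'   parameters.
#' @export
synthesize_case <- function(W = 10.24, peak_disp = 0.32, F_amp = NULL,
                            E = 1500, nu = 0.45, depth = 30.3,
                            volume_shape = c(512L, 512L, 32L),
                            spacing = c(0.16, 0.16, 0.3),
                            density = 0.0625, z_sigma = 0.15,
                            noise = noise_model(), seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  extent <- (volume_shape - 1L) * spacing
  ctr <- extent[1:2] / 2
  sub <- elastic_substrate(E, nu, depth = depth)
  scene <- if (is.null(F_amp))
    gaussian_traction_scene(W, sub, peak_disp = peak_disp, center = ctr)
  else gaussian_traction_scene(W, sub, F_amp = F_amp, center = ctr)
  ## the imaged area is one mirror-symmetric unit cell of the periodic
  ## sampler, so the fixed-bottom computational box with frictionless
  ## lateral walls reproduces the sampled mechanics exactly
  smp <- boussinesq_gaussian_sampler(
    scene, grid_spacing = W / 8,
    domain_half_width = max(extent[1], extent[2]) / 2,
    periodic_cell = if (is.finite(depth)) max(extent[1], extent[2]) else NULL)
  tmpl <- bead_template(spacing = spacing)
  z_mid <- extent[3] / 2
  spec <- bead_layer_spec(extent = extent[1:2], density = density,
                          z_mean = z_mid, z_sigma = z_sigma,
                          exclusion_radius = 1.0, seed = seed)
  beads <- seed_beads(spec)
  beads_def <- deform_beads(beads, smp)
  ref <- render_volume(beads, tmpl, volume_shape, spacing, noise,
                       noise_seed = seed * 2L + 1L)
  def <- render_volume(beads_def, tmpl, volume_shape, spacing, noise,
                       noise_seed = seed * 2L + 2L)
  structure(list(ref = ref, def = def, sampler = smp, beads_ref = beads,
                 beads_def = beads_def, template = tmpl, scene = scene,
                 spacing = spacing, volume_shape = volume_shape,
                 seed = seed),
            class = "tfm_case")
}

#' Locate an isolated bead suitable for PSF extraction
#'
#' Returns the voxel coordinates of the detected bead whose nearest
#' neighbour is farthest away while keeping the ROI inside the stack.
#'
#' @param volume a [volume_image()].
#' @param roi_half_size ROI half-size in voxels.
#' @param intensity_threshold detection threshold (fraction of max).
#' @return Integer voxel coordinates `(i, j, k)`.
#' @export
find_isolated_bead <- function(volume, roi_half_size = c(8L, 8L, 6L),
                               intensity_threshold = 0.3) {
  a <- volume$data
  bg <- stats::median(a)
  pk <- find_local_maxima(pmax(a - bg, 0),
                          intensity_threshold * max(a - bg))
  if (nrow(pk) == 0L) stop("no beads detected for PSF extraction")
  d <- dim(a)
  margin <- roi_half_size + 1L
  ok <- pk[, 1] > margin[1] & pk[, 1] <= d[1] - margin[1] &
    pk[, 2] > margin[2] & pk[, 2] <= d[2] - margin[2] &
    pk[, 3] > margin[3] & pk[, 3] <= d[3] - margin[3]
  pk <- pk[ok, , drop = FALSE]
  if (nrow(pk) == 0L) stop("no bead far enough from the stack border")
  if (nrow(pk) == 1L) return(pk[1, ])
  D <- as.matrix(stats::dist(pk))
  diag(D) <- Inf
  pk[which.max(apply(D, 1, min)), ]
}

#' Run the full reconstruction on a reference/deformed volume pair
#'
#' Executes the workflow: Richardson-Lucy deconvolution with an
#' empirically extracted PSF, subvoxel bead localization, topology-based
#' tracking, z-outlier rejection and plane fitting, curvature-regularized
#' planarization onto the FE top-surface grid, the neo-Hookean forward
#' solve, and Cauchy traction recovery.
#'
#' @param ref,def reference and deformed [volume_image()]s.
#' @param opts a [tfm_options()].
#' @return A list of class `tfm_result` with `psf`, `beads_ref`,
#'   `beads_def`, `tracked` (scattered field), `plane`, `grid` (planarized
#'   displacement), `mesh`, `solution`, `traction`, and a per-stage `log`.
#' @export
run_tfm <- function(ref, def, opts = tfm_options()) {
  stopifnot(inherits(ref, "volume_image"), inherits(def, "volume_image"))
  log <- list()
  t_all <- proc.time()[3]
  psf <- NULL
  if (isTRUE(opts$deconvolve)) {
    hint <- find_isolated_bead(ref, opts$psf_roi_half_size,
                               opts$intensity_threshold)
    psf <- extract_psf(ref, hint, opts$psf_roi_half_size)
    ref <- lucy_richardson(ref, psf, iterations = opts$decon_iterations)
    def <- lucy_richardson(def, psf, iterations = opts$decon_iterations)
    log$deconvolution <- list(psf_center = hint,
                              iterations = opts$decon_iterations)
  }
  beads_ref <- localize_beads(ref, opts$intensity_threshold,
                              opts$bead_radius_voxels)
  beads_def <- localize_beads(def, opts$intensity_threshold,
                              opts$bead_radius_voxels)
  log$localization <- list(n_ref = nrow(beads_ref), n_def = nrow(beads_def))
  tracked <- track(beads_ref, beads_def, k_neighbors = opts$k_neighbors,
                   max_disp = opts$max_disp,
                   n_iterations = opts$track_iterations,
                   outlier_threshold = opts$outlier_threshold)
  log$tracking <- list(n_links = nrow(tracked),
                       match_rate = attr(tracked, "match_rate"),
                       outliers_removed = attr(tracked, "n_outliers_removed"))
  tracked <- reject_z_outliers(tracked, opts$n_std)
  log$z_outliers_removed <- attr(tracked, "n_removed")
  plane <- fit_plane(tracked)
  ## computational frame = plane frame; mesh covers the projected data or
  ## the full imaged volume
  pc <- plane_coords(plane, cbind(tracked$x, tracked$y, tracked$z))
  base <- build_base_mesh(opts$mesh)
  if (identical(opts$domain, "volume")) {
    span <- (dim(ref$data)[1:2] - 1L) * ref$spacing[1:2]
    org <- ref$origin[1:2] - plane$point[1:2]
    ext <- c(span, opts$depth)
    origin <- c(org, -opts$depth)
  } else {
    ext <- c(diff(range(pc[, 1])), diff(range(pc[, 2])), opts$depth)
    origin <- c(min(pc[, 1]), min(pc[, 2]), -opts$depth)
  }
  mesh <- warp_mesh_to_volume(base, ext, origin = origin)
  grid <- regularized_resample(tracked, plane, top_surface_grid(mesh),
                               lambda_xy = opts$lambda_xy,
                               lambda_z = opts$lambda_z)
  material <- make_material(opts$material$E, opts$material$nu)
  extra_bc <- if (identical(opts$lateral_bc, "mirror")) {
    list(list(nodes = mesh$faces$right, comp = 1L, value = 0),
         list(nodes = mesh$faces$front, comp = 2L, value = 0))
  } else list()
  solution <- solve_forward(mesh, material, grid, extra_bc = extra_bc,
                            formulation = opts$formulation,
                            rtol = opts$rtol)
  log$newton <- lapply(solution$report$steps, `[[`, "iterations")
  tf <- surface_traction(solution)
  log$elapsed_s <- proc.time()[3] - t_all
  structure(list(psf = psf, beads_ref = beads_ref, beads_def = beads_def,
                 tracked = tracked, plane = plane, grid = grid, mesh = mesh,
                 solution = solution, traction = tf, opts = opts,
                 log = log),
            class = "tfm_result")
}

#' @export
print.tfm_result <- function(x, ...) {
  cat(sprintf(
    "<tfm_result> %d links (match rate %.1f%%), peak |u| = %.4g um, peak |T| = %.4g Pa\n",
    nrow(x$tracked), 100 * x$log$tracking$match_rate,
    max(sqrt(x$grid$ux^2 + x$grid$uy^2 + x$grid$uz^2)),
    max(x$traction$magnitude)))
  invisible(x)
}

#' Ground-truth fields of a synthetic case at the reconstruction grid nodes
#'
#' @param case a [synthesize_case()] result.
#' @param result a [run_tfm()] result for that case.
#' @return List with matrices `u_true`, `u_meas`, `t_true`, `t_meas`
#'   (n x 3) sampled at the top-surface grid nodes.
#' @export
case_truth <- function(case, result) {
  grid <- result$grid
  plane <- result$plane
  nxn <- length(grid$x); nyn <- length(grid$y)
  xi <- rep(grid$x, times = nyn); eta <- rep(grid$y, each = nxn)
  xyz <- matrix(plane$point, nxn * nyn, 3, byrow = TRUE) +
    outer(xi, plane$e1) + outer(eta, plane$e2)
  u_true <- case$sampler$u(xyz[, 1:2])
  t_true <- case$sampler$t(xyz[, 1:2])
  u_meas <- cbind(as.vector(grid$ux), as.vector(grid$uy),
                  as.vector(grid$uz))
  t_meas <- result$traction$traction
  list(u_true = u_true, u_meas = u_meas, t_true = t_true, t_meas = t_meas,
       xy = xyz[, 1:2])
}

#' Validate and normalize a pipeline configuration
#'
#' The file-driven entry point ([run_pipeline()]) is configured by a
#' single YAML (or list) configuration: stack paths, voxel spacing,
#' material constants, and any [tfm_options()] override.
#'
#' @param config path to a YAML file or a named list.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("reference", "deformed", "spacing", "output_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("config lacks required key(s): ", paste(missing, collapse = ", "))
  for (p in c(config$reference, config$deformed))
    if (!file.exists(p)) stop("stack path does not exist: ", p)
  config$spacing <- as.numeric(config$spacing)
  if (length(config$spacing) != 3L || any(config$spacing <= 0))
    stop("'spacing' must be 3 positive voxel sizes (um)")
  if (!is.null(config$crop)) {
    config$crop <- as.integer(config$crop)
    if (length(config$crop) != 6L) stop("'crop' must be 6 voxel bounds")
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the file-driven pipeline end to end
#'
#' Reads the reference and deformed TIFF stacks, optionally crops them,
#' runs [run_tfm()], and persists every intermediate product (bead sets
#' and displacements as CSV, meshes and solutions as legacy VTK, the
#' traction field as CSV, a JSON run manifest with configuration, seeds
#' and timings).
#'
#' @param config a [pipeline_config()], a list, or a YAML path.
#' @return The [run_tfm()] result, invisibly; side effect: files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- read_volume_tiff(config$reference, config$spacing)
  def <- read_volume_tiff(config$deformed, config$spacing)
  if (!is.null(config$crop)) {
    ref <- crop_volume(ref, config$crop)
    def <- crop_volume(def, config$crop)
  }
  keys <- intersect(names(config), names(tfm_options()))
  opts <- do.call(tfm_options, config[keys])
  res <- run_tfm(ref, def, opts)
  out <- config$output_dir
  utils::write.csv(res$beads_ref, file.path(out, "beads_reference.csv"),
                   row.names = FALSE)
  utils::write.csv(res$beads_def, file.path(out, "beads_deformed.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$tracked),
                   file.path(out, "displacements_scattered.csv"),
                   row.names = FALSE)
  write_grid_csv(res$grid, file.path(out, "displacement_grid.csv"))
  write_vtk_solution(res$solution, file.path(out, "solution.vtk"))
  write_traction_csv(res$traction, file.path(out, "traction.csv"))
  manifest <- list(config = unclass(config),
                   log = res$log,
                   versions = list(
                     package = as.character(utils::packageVersion("eftfm")),
                     r = R.version.string),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(res)
}
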