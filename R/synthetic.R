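#' Elastic substrate description for the analytic indentation fields
#'
#' Linear-elastic substrate on which the analytic Gaussian-indentation
#' solution is evaluated.  With `depth = Inf` this is the classical elastic
#' half-space; a finite `depth` describes a layer of thickness `depth`
#' bonded to a rigid base (displacement-free bottom), which matches the
#' finite-element domain used downstream (fixed bottom face) and therefore
#' yields a ground truth that is mechanically consistent with the forward
#' solve.
#'
#' @param E Young's modulus (Pa), `> 0`.
#' @param nu Poisson's ratio, in `[0, 0.5)` (the compressible formulation
#'   used throughout excludes the incompressible limit).
#' @param depth substrate thickness in um (`Inf` for a half-space).
#' @return An object of class `elastic_substrate` with fields `E`, `nu`,
#'   `depth` and derived Lame constants `mu`, `lambda`.
#' @examples
#' elastic_substrate(E = 1500, nu = 0.45)
#' @export
elastic_substrate <- function(E, nu, depth = Inf) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("'E' must be a positive Young's modulus in Pa")
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu >= 0.5)
    stop("'nu' must satisfy 0 <= nu < 0.5 (compressible formulation)")
  if (!(is.infinite(depth) || (is.finite(depth) && depth > 0)))
    stop("'depth' must be positive or Inf")
  structure(list(E = E, nu = nu, depth = depth,
                 mu = E / (2 * (1 + nu)),
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu))),
            class = "elastic_substrate")
}

#' Gaussian surface-traction indentation scene
#'
#' Describes a Gaussian out-of-plane (z) traction profile applied to the
#' substrate surface, parameterized by its full-width half-magnitude `W`.
#' Exactly one of the total force `F_amp` (nN) or the peak surface
#' displacement `peak_disp` (um) is prescribed; the other is derived from
#' the analytic solution when the sampler is built (the solution is linear,
#' so the two are proportional).
#'
#' @param W full-width half-magnitude of the Gaussian z-traction (um).
#' @param substrate an [elastic_substrate()].
#' @param F_amp total applied force (nN), positive for an upward pull.
#' @param peak_disp peak surface displacement magnitude (um).
#' @param center `(x, y)` position of the traction centre (um).
#' @return An object of class `gaussian_traction_scene`.
#' @examples
#' sub <- elastic_substrate(1500, 0.45)
#' gaussian_traction_scene(W = 10.24, substrate = sub, F_amp = 40)
#' @export
gaussian_traction_scene <- function(W, substrate, F_amp = NULL,
                                    peak_disp = NULL, center = c(0, 0)) {
  stopifnot(inherits(substrate, "elastic_substrate"))
  if (!is.numeric(W) || W <= 0) stop("'W' must be a positive width in um")
  if (is.null(F_amp) == is.null(peak_disp))
    stop("exactly one of 'F_amp' (nN) or 'peak_disp' (um) must be given")
  if (!is.null(F_amp) && F_amp < 0) stop("'F_amp' must be >= 0")
  if (!is.null(peak_disp) && peak_disp < 0) stop("'peak_disp' must be >= 0")
  structure(list(W = W, sigma = W / (2 * sqrt(2 * log(2))),
                 F_amp = F_amp, peak_disp = peak_disp,
                 center = as.numeric(center), substrate = substrate),
            class = "gaussian_traction_scene")
}

## ------------------------------------------------------------------------
## Surface compliance of the substrate in wavenumber space.
##
## For each wavenumber k the response of the layer (0 <= z <= h, bottom
## fixed, top loaded by t*cos(kx) normal traction with zero surface shear)
## follows from the plane-strain Navier equations, written as a first-order
## system in z and integrated exactly with a matrix exponential:
##   u_x = V(z) sin(kx),  u_z = W(z) cos(kx)
##   V'' = k^2 V + ((la+mu)/mu) k (k V + W')
##   (la+2mu) W'' = mu k^2 W - (la+mu) k V'
## Returns Czz = W(h)/t and Cxz = V(h)/t.  For kh -> Inf these approach the
## half-space values 2(1-nu^2)/(Ek) and (1+nu)(1-2nu)/(Ek); for kh -> 0 the
## normal compliance approaches confined compression h/(la+2mu).
## ------------------------------------------------------------------------

layer_compliance_1 <- function(k, E, nu, h) {
  mu <- E / (2 * (1 + nu)); la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  if (k * h > 12) {                       # half-space limit, error ~exp(-2kh)
    return(c(Czz = 2 * (1 - nu^2) / (E * k),
             Cxz = (1 + nu) * (1 - 2 * nu) / (E * k)))
  }
  a <- (la + mu) / mu
  M <- matrix(0, 4, 4)
  M[1, 2] <- 1
  M[2, 1] <- (1 + a) * k^2; M[2, 4] <- a * k
  M[3, 4] <- 1
  M[4, 3] <- mu * k^2 / (la + 2 * mu)
  M[4, 2] <- -(la + mu) * k / (la + 2 * mu)
  Phi <- pracma::expm(M * h)
  cp <- Phi[, 2]; cq <- Phi[, 4]          # V(0)=W(0)=0; unknown V'(0), W'(0)
  A <- rbind(c(cp[2] - k * cp[3], cq[2] - k * cq[3]),                # s_xz=0
             c(la * (k * cp[1] + cp[4]) + 2 * mu * cp[4],            # s_zz=t
               la * (k * cq[1] + cq[4]) + 2 * mu * cq[4]))
  pq <- solve(A, c(0, 1))
  y <- cp * pq[1] + cq * pq[2]
  c(Czz = y[3], Cxz = y[1])
}

layer_compliance <- function(k, E, nu, h) {
  out <- vapply(k, layer_compliance_1, numeric(2), E = E, nu = nu, h = h)
  list(Czz = out[1, ], Cxz = out[2, ])
}

## Closed-form half-space surface response to a Gaussian normal traction
## t_z(r) = t0 exp(-r^2 / (2 s^2)): the Fourier-space convolution with the
## Boussinesq surface Green's function evaluated in the continuum limit
## (Hankel integrals), so it is free of periodic-grid artifacts.
##   u_z(r) = (1-nu^2) t0 s sqrt(2 pi)/E * exp(-x) I0(x),  x = r^2/(4 s^2)
##   u_r(r) = (1+nu)(1-2nu) F_enc(r) / (2 pi E r),  F_enc = F (1 - e^{-r^2/2s^2})
## (u_r points away from an upward pull; classical Boussinesq sign.)

halfspace_gaussian_uz <- function(r, t0, s, E, nu) {
  x <- r^2 / (4 * s^2)
  (1 - nu^2) * t0 * s * sqrt(2 * pi) / E *
    besselI(x, 0, expon.scaled = TRUE)
}

halfspace_gaussian_ur <- function(r, t0, s, E, nu) {
  Ftot <- t0 * 2 * pi * s^2
  Fenc <- Ftot * (1 - exp(-r^2 / (2 * s^2)))
  out <- (1 + nu) * (1 - 2 * nu) * Fenc / (2 * pi * E * pmax(r, 1e-12))
  out[r == 0] <- 0
  out
}

#' Analytic surface displacement/traction sampler for a Gaussian indentation
#'
#' Builds the analytic solution for a Gaussian z-traction applied to the
#' substrate surface by convolving the load with the substrate's surface
#' Green's function in Fourier space.  For a half-space substrate
#' (`depth = Inf`) the convolution is evaluated in the continuum limit via
#' its closed forms; for a finite-thickness bonded layer it is evaluated on
#' a discrete Fourier grid using the per-wavenumber layer compliance, and
#' values between grid points are interpolated bilinearly.  The sampler is
#' normalized so that either the total applied force equals `scene$F_amp`
#' or the peak displacement magnitude equals `scene$peak_disp`.
#'
#' Units: displacements um, tractions Pa, forces nN (1 nN = 1e-3 Pa um^2
#' ... specifically 1 nN / um^2 = 1000 Pa; conversions are internal).
#'
#' @param scene a [gaussian_traction_scene()].
#' @param grid_spacing evaluation grid spacing (um); must be `<= W/8` so
#'   the Gaussian is resolved.
#' @param domain_half_width half-width of the evaluation domain (um); must
#'   be `>= 5 W` so the traction has decayed to a negligible fraction of
#'   its peak at the boundary.
#' @param periodic_cell optional exact period (um) of the discrete Fourier
#'   cell for the finite-thickness kernel.  When the downstream
#'   computational domain is one mirror-symmetric unit cell of a periodic
#'   array (frictionless-wall lateral faces), setting `periodic_cell` to
#'   the domain size makes the sampled field and the finite-element
#'   boundary-value problem describe identical mechanics, so global force
#'   balance closes to discretization error.  By default a generously
#'   padded cell is used instead, approximating an isolated load.
#' @return An object of class `analytic_field_sampler` with elements
#'   `u(xy)` and `t(xy)` (functions mapping an n x 2 matrix of surface
#'   positions to n x 3 displacement (um) / traction (Pa) matrices), the
#'   derived `F_amp` (nN), `peak_disp` (um), `t0` (peak traction, Pa) and
#'   the originating `scene`.
#' @examples
#' sub <- elastic_substrate(1500, 0.45)
#' sc <- gaussian_traction_scene(10.24, sub, F_amp = 40)
#' smp <- boussinesq_gaussian_sampler(sc, grid_spacing = 1.2,
#'                                    domain_half_width = 52)
#' smp$u(cbind(0, 0))        # peak displacement (um)
#' @export
boussinesq_gaussian_sampler <- function(scene, grid_spacing,
                                        domain_half_width,
                                        periodic_cell = NULL) {
  stopifnot(inherits(scene, "gaussian_traction_scene"))
  sub <- scene$substrate
  if (sub$nu >= 0.5)
    stop("nu >= 0.5: Green's function formulation assumes compressibility")
  if (grid_spacing > scene$W / 8 + 1e-12)
    stop("grid_spacing must be <= W/8 to resolve the Gaussian profile")
  ## decay containment: the Gaussian traction must be negligible at the
  ## domain boundary.  At r = W it is ~6% of peak (the worst case used in
  ## the large-width validation sweeps); below that the scene is rejected.
  if (domain_half_width < scene$W - 1e-9)
    stop("domain too small: need domain_half_width >= W for decay containment")
  s <- scene$sigma
  E <- sub$E; nu <- sub$nu
  ctr <- scene$center

  ## peak displacement per unit force (F = 1 nN); 1 nN/um^2 = 1000 Pa
  if (is.infinite(sub$depth)) {
    u_fun_unit <- function(xy) {       # displacement for F = 1 nN, um
      dx <- xy[, 1] - ctr[1]; dy <- xy[, 2] - ctr[2]
      r <- sqrt(dx^2 + dy^2)
      t0u <- 1000 / (2 * pi * s^2)                 # Pa for F = 1 nN
      uz <- halfspace_gaussian_uz(r, t0u, s, E, nu)
      ur <- halfspace_gaussian_ur(r, t0u, s, E, nu)
      ux <- ifelse(r > 0, ur * dx / r, 0)
      uy <- ifelse(r > 0, ur * dy / r, 0)
      cbind(ux, uy, uz)
    }
    peak_unit <- (1 - nu^2) * 1000 / (2 * pi * s^2) * s * sqrt(2 * pi) / E
    grid <- NULL
  } else {
    ## discrete Fourier-space convolution on a periodic cell; by default
    ## the padding keeps the periodic images of the load far enough that
    ## their tails are negligible inside the evaluation domain
    h <- sub$depth
    if (is.null(periodic_cell)) {
      cell_half <- max(domain_half_width * 2.5, 4 * h, 5 * scene$W)
    } else {
      if (periodic_cell < 2 * domain_half_width - 1e-9)
        stop("periodic_cell must cover the evaluation domain")
      cell_half <- periodic_cell / 2
    }
    n <- 2^ceiling(log2(2 * cell_half / grid_spacing))
    n <- max(n, 64)
    d <- 2 * cell_half / n
    kx <- 2 * pi * c(0:(n / 2), (-n / 2 + 1):(-1)) / (n * d)
    KX <- matrix(kx, n, n); KY <- t(KX)
    K <- sqrt(KX^2 + KY^2)
    ku <- sort(unique(as.vector(K)))
    ## compliance table over |k| (spline through exact values)
    kt <- ku[ku > 0]
    ktab <- exp(seq(log(min(kt)), log(max(kt)), length.out = 160))
    ct <- layer_compliance(ktab, E, nu, h)
    Czz <- function(k) {
      out <- numeric(length(k))
      pos <- k > 0
      out[pos] <- stats::spline(log(ktab), ct$Czz, xout = log(k[pos]),
                                method = "natural")$y
      out[!pos] <- layer_compliance_1(1e-9, E, nu, h)[["Czz"]]  # DC: h/M
      out
    }
    Cxz <- function(k) {
      out <- numeric(length(k))
      pos <- k > 0
      out[pos] <- stats::spline(log(ktab), ct$Cxz, xout = log(k[pos]),
                                method = "natural")$y
      out
    }
    t0u <- 1000 / (2 * pi * s^2)                   # Pa for F = 1 nN
    That <- t0u * 2 * pi * s^2 * exp(-K^2 * s^2 / 2)   # continuous FT, Pa um^2
    CzzK <- matrix(Czz(as.vector(K)), n, n)
    CxzK <- matrix(Cxz(as.vector(K)), n, n)
    Uz <- CzzK * That
    Kn <- K; Kn[1, 1] <- 1
    ## u_j(k) = -i (k_j/|k|) Cxz(|k|) t(k)   (t cos -> V sin convention)
    Ux <- -1i * (KX / Kn) * CxzK * That
    Uy <- -1i * (KY / Kn) * CxzK * That
    inv <- function(Uk) Re(stats::fft(Uk, inverse = TRUE)) / (n * n * d * d)
    uzg <- inv(Uz); uxg <- inv(Ux); uyg <- inv(Uy)
    ## grid coordinates centred on the scene centre; one wrapped row and
    ## column of periodic continuation so the full closed cell is covered
    sh <- n / 2
    roll <- function(m) {
      m <- m[c((sh + 1):n, 1:sh), c((sh + 1):n, 1:sh)]
      rbind(cbind(m, m[, 1]), c(m[1, ], m[1, 1]))
    }
    uzg <- roll(uzg); uxg <- roll(uxg); uyg <- roll(uyg)
    xg <- (seq_len(n + 1) - 1 - sh) * d
    grid <- list(x = xg + ctr[1], y = xg + ctr[2],
                 ux = uxg, uy = uyg, uz = uzg, spacing = d)
    ## the synthesized field is periodic with the cell, so queries within
    ## a small margin beyond the closed cell (tilt projection round-off at
    ## domain corners) are answered by periodic wrapping; anything farther
    ## out is genuinely outside the sampler domain and yields NA
    cell <- 2 * cell_half
    margin <- 0.02 * cell
    wrap_edge <- function(p, lo, hi) {
      p[p > hi & p <= hi + margin] <- p[p > hi & p <= hi + margin] - cell
      p[p < lo & p >= lo - margin] <- p[p < lo & p >= lo - margin] + cell
      p
    }
    interp_g <- function(M, px, py) {
      px <- wrap_edge(px, grid$x[1], grid$x[length(grid$x)])
      py <- wrap_edge(py, grid$y[1], grid$y[length(grid$y)])
      pracma::interp2(grid$y, grid$x, M, py, px, method = "linear")
    }
    u_fun_unit <- function(xy) {
      cbind(interp_g(uxg, xy[, 1], xy[, 2]),
            interp_g(uyg, xy[, 1], xy[, 2]),
            interp_g(uzg, xy[, 1], xy[, 2]))
    }
    peak_unit <- max(sqrt(uxg^2 + uyg^2 + uzg^2))
  }

  if (!is.null(scene$F_amp)) {
    F_amp <- scene$F_amp
    peak_disp <- F_amp * peak_unit
  } else {
    if (peak_unit <= 0 && scene$peak_disp > 0)
      stop("degenerate scene: zero compliance")
    F_amp <- if (scene$peak_disp == 0) 0 else scene$peak_disp / peak_unit
    peak_disp <- scene$peak_disp
  }
  t0 <- F_amp * 1000 / (2 * pi * s^2)              # peak traction, Pa

  u_fun <- function(xy) {
    xy <- matrix(as.numeric(xy), ncol = 2)
    if (F_amp == 0) return(matrix(0, nrow(xy), 3))
    F_amp * u_fun_unit(xy)
  }
  t_fun <- function(xy) {
    xy <- matrix(as.numeric(xy), ncol = 2)
    r2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
    cbind(0, 0, t0 * exp(-r2 / (2 * s^2)))
  }
  structure(list(u = u_fun, t = t_fun, F_amp = F_amp, peak_disp = peak_disp,
                 t0 = t0, scene = scene, grid = grid,
                 grid_spacing = grid_spacing,
                 domain_half_width = domain_half_width),
            class = "analytic_field_sampler")
}

#' @export
print.analytic_field_sampler <- function(x, ...) {
  cat(sprintf(
    "<analytic_field_sampler> W = %.3g um, F = %.4g nN, peak |u| = %.4g um, peak t = %.4g Pa (%s)\n",
    x$scene$W, x$F_amp, x$peak_disp, x$t0,
    if (is.infinite(x$scene$substrate$depth)) "half-space"
    else sprintf("layer h = %.3g um", x$scene$substrate$depth)))
  invisible(x)
}

#' Specification of a random near-planar bead layer
#'
#' @param extent lateral extent `(Lx, Ly)` of the seeded region (um).
#' @param density mean in-plane bead density (beads/um^2).
#' @param z_mean,z_sigma mean and standard deviation of the bead layer
#'   z-height (um).
#' @param exclusion_radius minimum allowed centre-to-centre distance (um).
#' @param seed integer RNG seed; seeding is fully reproducible.
#' @return An object of class `bead_layer_spec`.
#' @export
bead_layer_spec <- function(extent, density, z_mean = 0, z_sigma = 0.15,
                            exclusion_radius = 1.0, seed = 1L) {
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 2L, all(extent > 0))
  if (density <= 0) stop("'density' must be positive (beads/um^2)")
  if (exclusion_radius < 0) stop("'exclusion_radius' must be >= 0")
  if (z_sigma < 0) stop("'z_sigma' must be >= 0")
  structure(list(extent = extent, density = density, z_mean = z_mean,
                 z_sigma = z_sigma, exclusion_radius = exclusion_radius,
                 seed = as.integer(seed)),
            class = "bead_layer_spec")
}

#' Seed a random non-overlapping bead layer
#'
#' Draws a Poisson number of beads at the requested density, places them
#' uniformly in the lateral extent by dart-throwing subject to the
#' exclusion radius, and draws z-heights from a normal distribution.  The
#' result is deterministic for a given `spec$seed`.
#'
#' @param spec a [bead_layer_spec()].
#' @param origin lateral offset (um) added to the seeded `(x, y)` positions.
#' @return A `bead_set`: a data.frame with columns `x`, `y`, `z` (um).
#' @export
seed_beads <- function(spec, origin = c(0, 0)) {
  stopifnot(inherits(spec, "bead_layer_spec"))
  area <- prod(spec$extent)
  with_seed(spec$seed, {
    n_target <- stats::rpois(1, spec$density * area)
    if (spec$exclusion_radius > min(spec$extent) / 2 && n_target > 1)
      stop("packing failure: exclusion radius exceeds the seeded extent")
    pos <- matrix(NA_real_, n_target, 2)
    n <- 0L
    tries <- 0L
    max_tries <- 200L * max(n_target, 1L)
    r2min <- spec$exclusion_radius^2
    while (n < n_target && tries < max_tries) {
      tries <- tries + 1L
      cand <- stats::runif(2) * spec$extent
      ok <- TRUE
      if (n > 0L && r2min > 0) {
        d2 <- (pos[1:n, 1] - cand[1])^2 + (pos[1:n, 2] - cand[2])^2
        ok <- all(d2 >= r2min)
      }
      if (ok) { n <- n + 1L; pos[n, ] <- cand }
    }
    if (n < n_target)
      stop(sprintf(
        "packing failure: placed %d of %d beads under exclusion radius %.3g um",
        n, n_target, spec$exclusion_radius))
    z <- stats::rnorm(n, spec$z_mean, spec$z_sigma)
    out <- data.frame(x = pos[1:n, 1] + origin[1],
                      y = pos[1:n, 2] + origin[2], z = z)
    class(out) <- c("bead_set", "data.frame")
    out
  })
}

#' Additive image-noise model for synthetic stacks
#'
#' Gaussian white read noise plus a constant fluorescence background;
#' intensities are clipped to the dynamic range after corruption.  Defaults
#' are a 2% read-noise floor and a 5% background on a unit dynamic range,
#' typical of sCMOS epifluorescence imaging.
#'
#' @param gaussian_sigma additive noise standard deviation (intensity units).
#' @param background constant offset (intensity units).
#' @param dynamic_range length-2 `(min, max)` clip values.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0.02, background = 0.05,
                        dynamic_range = c(0, 1)) {
  if (gaussian_sigma < 0) stop("'gaussian_sigma' must be >= 0")
  dynamic_range <- as.numeric(dynamic_range)
  if (diff(dynamic_range) <= 0) stop("dynamic_range max must exceed min")
  structure(list(gaussian_sigma = gaussian_sigma, background = background,
                 dynamic_range = dynamic_range),
            class = "noise_model")
}

#' Synthetic single-bead intensity template
#'
#' An anisotropic Gaussian blob emulating the epifluorescence image of a
#' 0.5 um bead: narrow in-plane, elongated along z by out-of-focus light.
#' Used both to render synthetic bead layers and (via [extract_psf()]) as
#' the deconvolution kernel.
#'
#' @param spacing voxel spacing `(dx, dy, dz)` in um.
#' @param sigma_xy,sigma_z Gaussian widths (um).
#' @param half_size patch half-size in voxels `(hx, hy, hz)`.
#' @param amplitude peak intensity.
#' @return A [volume_image()] holding the template patch (odd dimensions).
#' @export
bead_template <- function(spacing = c(0.16, 0.16, 0.3), sigma_xy = 0.30,
                          sigma_z = 1.35, half_size = c(7, 7, 9),
                          amplitude = 0.85) {
  hs <- as.integer(half_size)
  ax <- (-hs[1]:hs[1]) * spacing[1]
  ay <- (-hs[2]:hs[2]) * spacing[2]
  az <- (-hs[3]:hs[3]) * spacing[3]
  g <- outer(outer(exp(-ax^2 / (2 * sigma_xy^2)),
                   exp(-ay^2 / (2 * sigma_xy^2))),
             exp(-az^2 / (2 * sigma_z^2)))
  volume_image(amplitude * g, spacing,
               origin = -hs * spacing)
}

## internal: shift a small patch by a subvoxel offset via Fourier phase
## (exact for band-limited signals; the patch is zero-padded so the
## periodic wrap has no support inside the template)

fourier_shift_patch <- function(patch, shift, pad = 3L) {
  if (all(abs(shift) < 1e-12)) return(patch)   # bitwise no-op for zero shift
  d <- dim(patch)
  dp <- d + 2L * pad
  big <- array(0, dp)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- patch
  ks <- lapply(dp, function(n) {
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    if (n %% 2 == 0) k[n %/% 2 + 1] <- abs(k[n %/% 2 + 1])
    k
  })
  ph <- exp(-2i * pi * (outer(outer(ks[[1]] * shift[1],
                                    ks[[2]] * shift[2], "+"),
                              ks[[3]] * shift[3], "+")))
  out <- Re(stats::fft(stats::fft(big) * ph, inverse = TRUE)) / prod(dp)
  ## crop back to the template footprint (the shifted tails that leave it
  ## are below the band-limited template's numerical floor)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]),
      drop = FALSE]
}

#' Render a bead set into a synthetic volume image
#'
#' Inserts a copy of the single-bead template at each bead position with
#' subvoxel accuracy (Fourier phase shift inside a zero-padded patch, i.e.
#' minimal-interpolation placement), sums overlapping templates, then adds
#' the background and Gaussian white noise and clips to the dynamic range.
#'
#' @param beads a `bead_set` (data.frame with `x`, `y`, `z` in um).
#' @param template single-bead [volume_image()] patch (odd dimensions, same
#'   spacing as the output volume).
#' @param volume_shape integer `(nx, ny, nz)` voxel counts.
#' @param voxel_spacing `(dx, dy, dz)` in um.
#' @param noise a [noise_model()]; use `gaussian_sigma = 0` for noiseless.
#' @param origin physical position (um) of voxel `(1,1,1)`.
#' @param noise_seed RNG seed for the noise realization.
#' @return A [volume_image()] of the rendered stack.
#' @export
render_volume <- function(beads, template, volume_shape,
                          voxel_spacing = template$spacing,
                          noise = noise_model(), origin = c(0, 0, 0),
                          noise_seed = 1L) {
  stopifnot(inherits(template, "volume_image"))
  volume_shape <- as.integer(volume_shape)
  if (any(dim(template$data) >= volume_shape))
    stop("template must be strictly smaller than the output volume")
  if (max(abs(template$spacing - voxel_spacing)) > 1e-9)
    stop("template spacing must match the output voxel spacing")
  vol <- array(0, volume_shape)
  td <- dim(template$data)
  th <- (td - 1L) %/% 2L
  if (nrow(beads) == 0L)
    warning("empty bead set: rendering background + noise only")
  n_clip <- 0L
  pad <- 3L
  for (b in seq_len(nrow(beads))) {
    p <- (c(beads$x[b], beads$y[b], beads$z[b]) - origin) / voxel_spacing + 1
    ijk <- round(p)
    frac <- p - ijk
    patch <- fourier_shift_patch(template$data, frac, pad = pad)
    ph <- (dim(patch) - 1L) %/% 2L
    lo <- as.integer(ijk) - ph
    hi <- as.integer(ijk) + ph
    if (any(hi < 1L) || any(lo > volume_shape)) { n_clip <- n_clip + 1L; next }
    slo <- pmax(lo, 1L); shi <- pmin(hi, volume_shape)
    if (any(slo > lo) || any(shi < hi)) n_clip <- n_clip + 1L
    vol[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]] <-
      vol[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]] +
      patch[(slo[1] - lo[1] + 1L):(shi[1] - lo[1] + 1L),
            (slo[2] - lo[2] + 1L):(shi[2] - lo[2] + 1L),
            (slo[3] - lo[3] + 1L):(shi[3] - lo[3] + 1L)]
  }
  if (n_clip > 0L)
    warning(sprintf("%d bead(s) clipped at the volume boundary", n_clip))
  vol <- vol + noise$background
  if (noise$gaussian_sigma > 0) {
    vol <- vol + with_seed(noise_seed,
      array(stats::rnorm(length(vol), 0, noise$gaussian_sigma), dim(vol)))
  }
  vol <- pmin(pmax(vol, noise$dynamic_range[1]), noise$dynamic_range[2])
  volume_image(vol, voxel_spacing, origin)
}

#' Displace beads by the analytic surface field
#'
#' Each bead is translated by the 3D analytic displacement evaluated at its
#' lateral position.  Row order (and therefore ground-truth correspondence
#' between reference and deformed sets) is preserved.
#'
#' @param beads a `bead_set`.
#' @param sampler an [boussinesq_gaussian_sampler()] result.
#' @return The displaced `bead_set`.
#' @export
deform_beads <- function(beads, sampler) {
  stopifnot(inherits(sampler, "analytic_field_sampler"))
  if (nrow(beads) == 0L) return(beads)
  u <- sampler$u(cbind(beads$x, beads$y))
  if (any(!is.finite(u)))
    stop("bead outside the sampler's analytic domain")
  out <- beads
  out$x <- beads$x + u[, 1]
  out$y <- beads$y + u[, 2]
  out$z <- beads$z + u[, 3]
  out
}
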