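# Synthetic bead scenes: ground truth containers and renderers that stand in
# for the instrument (bead samples on cover glass and in agarose), with
# injected PSF field, radial magnification distortion, scan illumination
# gradient, and camera noise.

#' Gaussian FWHM / sigma conversion factor, 2*sqrt(2*log(2))
#' @export
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

#' Spatially varying Gaussian PSF model
#'
#' FWHMs grow linearly with radial distance from the image centre and with
#' absolute depth from the focal plane:
#' `fwhm = fwhm0 * (1 + radial_growth * r + depth_growth * |z|)`,
#' with `r`, `z` in micrometres. Defaults emulate a remote-focusing path whose
#' lateral FWHM grows from 255 nm on axis to ~272 nm at a 100 um radius and
#' whose axial FWHM grows ~27% over 10 um of defocus.
#'
#' @param fwhm_lat0 Lateral FWHM at centre/focus (nm).
#' @param fwhm_ax0 Axial FWHM at centre/focus (nm), `>= fwhm_lat0`.
#' @param radial_growth Fractional FWHM increase per um of radial distance.
#' @param depth_growth_lat,depth_growth_ax Fractional increase per um of |depth|.
#' @return An object of class `psf_field_model`.
#' @export
psf_field_model <- function(fwhm_lat0 = 255, fwhm_ax0 = 688,
                            radial_growth = 6.7e-4,
                            depth_growth_lat = 0.009,
                            depth_growth_ax = 0.027) {
  if (fwhm_lat0 <= 0 || fwhm_ax0 < fwhm_lat0) {
    stop("require fwhm_ax0 >= fwhm_lat0 > 0", call. = FALSE)
  }
  if (radial_growth < 0 || depth_growth_lat < 0 || depth_growth_ax < 0) {
    stop("growth coefficients must be >= 0", call. = FALSE)
  }
  structure(list(fwhm_lat0 = fwhm_lat0, fwhm_ax0 = fwhm_ax0,
                 radial_growth = radial_growth,
                 depth_growth_lat = depth_growth_lat,
                 depth_growth_ax = depth_growth_ax),
            class = "psf_field_model")
}

#' Evaluate the PSF field at a bead location
#'
#' @param model A [psf_field_model()].
#' @param r Radial distance from the image centre (um).
#' @param depth Depth from the focal plane (um, sign ignored).
#' @return List with `fwhm_lat` and `fwhm_ax` in nm (vectorized over r/depth).
#' @export
psf_fwhm_at <- function(model, r, depth = 0) {
  list(
    fwhm_lat = model$fwhm_lat0 *
      (1 + model$radial_growth * r + model$depth_growth_lat * abs(depth)),
    fwhm_ax = model$fwhm_ax0 *
      (1 + model$radial_growth * r + model$depth_growth_ax * abs(depth))
  )
}

#' Ground truth for a synthetic bead scene
#'
#' @param positions Data frame with columns `x`, `y`, `z` (um, sample space,
#'   origin at the image centre / focal plane).
#' @param flux Expected photon count per bead (integrated, counts).
#' @param psf_model A [psf_field_model()].
#' @param distortion_rate Radial magnification error per um of depth
#'   (fraction/um); apparent lateral positions scale by
#'   `1 + distortion_rate * z` about the image centre.
#' @param ratio_opt_map Numeric `c(a, b)`: optimal mirror voltage ratio as a
#'   function of objective Z position (mm), `ratio_opt(z) = a + b * z`.
#' @param gradient_gain Illumination intensity slope per scan step per unit of
#'   mirror-ratio mismatch.
#' @param fov Extents `c(x, y, z)` (um) the positions were drawn from.
#' @param seed RNG seed recorded for reproducibility.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(positions, flux = 13000, psf_model = psf_field_model(),
                        distortion_rate = 0,
                        ratio_opt_map = c(a = 1.014, b = 0.0028),
                        gradient_gain = 0.5, fov = NULL, seed = NA_integer_) {
  stopifnot(is.data.frame(positions),
            all(c("x", "y", "z") %in% names(positions)))
  if (flux <= 0) stop("flux must be > 0", call. = FALSE)
  if (!is.null(fov)) {
    half <- fov / 2
    inside <- abs(positions$x) <= half[1] + 1e-9 &
      abs(positions$y) <= half[2] + 1e-9 &
      abs(positions$z) <= half[3] + 1e-9
    if (!all(inside)) stop("bead positions outside declared FOV", call. = FALSE)
  }
  structure(list(positions = positions, flux = flux, psf_model = psf_model,
                 distortion_rate = distortion_rate,
                 ratio_opt_map = c(a = unname(ratio_opt_map[1]),
                                   b = unname(ratio_opt_map[2])),
                 gradient_gain = gradient_gain, fov = fov, seed = seed),
            class = "scene_truth")
}

#' Optimal mirror voltage ratio at an objective position (ground truth)
#'
#' @param truth A [scene_truth()].
#' @param objective_z Objective Z position (mm).
#' @return The injected optimal ratio `a + b * objective_z`.
#' @export
truth_ratio_opt <- function(truth, objective_z) {
  truth$ratio_opt_map[["a"]] + truth$ratio_opt_map[["b"]] * objective_z
}

#' Draw a random bead field
#'
#' Uniform positions inside a centred box, with an optional minimum pairwise
#' separation enforced by rejection sampling (`min_separation = 0` skips the
#' check, appropriate for dense agarose-like fields).
#'
#' @param fov Extents `c(x, y, z)` in um; a zero extent collapses that axis
#'   (e.g. beads immobilized on a coverslip have `fov[3] = 0`).
#' @param n_beads Number of beads (>= 1).
#' @param min_separation Minimum pairwise distance (um).
#' @param seed RNG seed; the draw is reproducible bit-for-bit.
#' @param ... Passed on to [scene_truth()] (flux, psf_model, distortion_rate,
#'   ratio_opt_map, gradient_gain).
#' @return A [scene_truth()].
#' @export
generate_bead_field <- function(fov, n_beads, min_separation = 0, seed = 1,
                                ...) {
  stopifnot(length(fov) == 3, all(fov >= 0), n_beads >= 1)
  set.seed(seed)
  half <- fov / 2
  draw <- function(n) {
    data.frame(x = stats::runif(n, -half[1], half[1]),
               y = stats::runif(n, -half[2], half[2]),
               z = stats::runif(n, -half[3], half[3]))
  }
  if (min_separation <= 0 || n_beads == 1) {
    pos <- draw(n_beads)
  } else {
    pos <- draw(1)
    tries <- 0L
    cap <- 200L * n_beads
    while (nrow(pos) < n_beads) {
      cand <- draw(1)
      d2 <- (pos$x - cand$x)^2 + (pos$y - cand$y)^2 + (pos$z - cand$z)^2
      if (min(d2) >= min_separation^2) {
        pos <- rbind(pos, cand)
      } else {
        tries <- tries + 1L
        if (tries > cap) {
          stop("bead density infeasible: rejection sampling exceeded ",
               cap, " attempts", call. = FALSE)
        }
      }
    }
  }
  scene_truth(positions = pos, fov = fov, seed = seed, ...)
}

#' Camera noise model
#'
#' @param poisson Apply Poisson shot noise to the expected counts.
#' @param read_sigma Gaussian read noise standard deviation (counts).
#' @return A `noise_model` list. `noise_model(FALSE, 0)` is the noise-free limit.
#' @export
noise_model <- function(poisson = TRUE, read_sigma = 1.6) {
  structure(list(poisson = poisson, read_sigma = read_sigma),
            class = "noise_model")
}

# Apply the camera noise model to an array of expected counts. Values are
# clamped at zero (counts cannot be negative); with the default near-zero
# background this clamp only trims the lower tail of the read noise.
apply_camera_noise <- function(arr, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- arr
  if (isTRUE(noise$poisson)) {
    out[] <- stats::rpois(length(out), lambda = pmax(out, 0))
  }
  if (noise$read_sigma > 0) {
    out <- out + stats::rnorm(length(out), sd = noise$read_sigma)
  }
  pmax(out, 0)
}

#' Straight-path stack geometry
#'
#' @param nx,ny Frame size in pixels.
#' @param nz Number of planes.
#' @param pixel_xy Lateral pixel size (um); default 0.1083 um (6.5 um camera
#'   pixel through the 60X straight analysis path).
#' @param step_z Plane spacing (um); default 0.15 um over 54 planes, the
#'   tertiary-objective scan used for PSF stacks.
#' @param z_centre Depth at which the stack is centred (um), i.e. the sample
#'   piezo position for a depth series.
#' @return A `stack_geometry` list.
#' @export
stack_geometry <- function(nx, ny, nz = 54, pixel_xy = 0.1083, step_z = 0.15,
                           z_centre = 0) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, pixel_xy > 0, step_z > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 pixel_xy = pixel_xy, step_z = step_z, z_centre = z_centre),
            class = "stack_geometry")
}

#' Bead image stack
#'
#' Container for a 3D intensity volume plus voxel geometry. Straight-path
#' stacks hold voxels indexed `[y, x, z]` with the image centre at 0-based
#' pixel `((nx-1)/2, (ny-1)/2)`; oblique scan series hold voxels indexed
#' `[y, oblique, step]`.
#'
#' @param voxels 3D numeric array of non-negative intensities.
#' @param modality `"straight"` or `"oblique"`.
#' @param pixel_xy Lateral pixel size (um; straight modality).
#' @param step_z Plane spacing (um; straight modality).
#' @param z_centre Depth of the stack centre (um; straight modality).
#' @param pixel_y,pixel_obl Pixel sizes along camera Y and the oblique axis
#'   (um; oblique modality).
#' @param scan_step Mirror scan step along X (um; oblique modality).
#' @param tilt_deg Tilt of the oblique plane (degrees; oblique modality).
#' @return An object of class `bead_stack`.
#' @export
bead_stack <- function(voxels, modality = c("straight", "oblique"),
                       pixel_xy = NULL, step_z = NULL, z_centre = 0,
                       pixel_y = NULL, pixel_obl = NULL, scan_step = NULL,
                       tilt_deg = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (min(voxels) < 0) stop("voxel values must be >= 0", call. = FALSE)
  if (modality == "straight") {
    stopifnot(!is.null(pixel_xy), pixel_xy > 0, !is.null(step_z), step_z > 0)
  } else {
    if (is.null(tilt_deg)) {
      stop("oblique modality requires tilt_deg", call. = FALSE)
    }
    stopifnot(pixel_y > 0, pixel_obl > 0, scan_step > 0,
              tilt_deg > 0, tilt_deg < 90)
  }
  structure(list(voxels = voxels, modality = modality, pixel_xy = pixel_xy,
                 step_z = step_z, z_centre = z_centre, pixel_y = pixel_y,
                 pixel_obl = pixel_obl, scan_step = scan_step,
                 tilt_deg = tilt_deg),
            class = "bead_stack")
}

#' @export
print.bead_stack <- function(x, ...) {
  d <- dim(x$voxels)
  if (x$modality == "straight") {
    cat(sprintf("bead_stack [straight] %d x %d px, %d planes, %.4f um/px, %.3f um/plane, centred at z = %g um\n",
                d[2], d[1], d[3], x$pixel_xy, x$step_z, x$z_centre))
  } else {
    cat(sprintf("bead_stack [oblique, %g deg] %d x %d px, %d steps, y %.4f / obl %.4f um/px, %.4f um/step\n",
                x$tilt_deg, d[2], d[1], d[3], x$pixel_y, x$pixel_obl,
                x$scan_step))
  }
  invisible(x)
}

# Per-bead apparent state under the injected field model: distorted lateral
# position and local FWHMs (sigma in um).
bead_render_params <- function(truth, depth_override = NULL) {
  p <- truth$positions
  z <- if (is.null(depth_override)) p$z else rep(depth_override, nrow(p))
  r <- sqrt(p$x^2 + p$y^2)
  scale <- 1 + truth$distortion_rate * z
  fw <- psf_fwhm_at(truth$psf_model, r, z)
  data.frame(
    x_app = p$x * scale, y_app = p$y * scale, z = z, r = r,
    sigma_lat = fw$fwhm_lat / 1000 / FWHM_SIGMA,
    sigma_ax = fw$fwhm_ax / 1000 / FWHM_SIGMA
  )
}

#' Render a straight-path Z-stack of a bead scene
#'
#' Each bead is rendered as a separable 3D Gaussian whose FWHMs are the PSF
#' field evaluated at the bead's (radius, depth); apparent lateral positions
#' are scaled by `1 + distortion_rate * z` about the image centre; camera
#' noise is applied last. The noise-free expected counts of a bead integrate
#' to `flux` up to truncation at the stack borders.
#'
#' @param truth A [scene_truth()].
#' @param geometry A [stack_geometry()].
#' @param noise A [noise_model()]; `noise_model(FALSE, 0)` renders noise-free.
#' @param seed Seed for the noise draw (optional; the expected image is
#'   deterministic given `truth`).
#' @return A straight-modality [bead_stack()].
#' @export
render_stack <- function(truth, geometry, noise = noise_model(), seed = NULL) {
  g <- geometry
  pars <- bead_render_params(truth)
  arr <- array(0, dim = c(g$ny, g$nx, g$nz))
  cx0 <- (g$nx - 1) / 2
  cy0 <- (g$ny - 1) / 2
  cz0 <- (g$nz - 1) / 2
  for (b in seq_len(nrow(pars))) {
    sx <- pars$sigma_lat[b] / g$pixel_xy
    sz <- pars$sigma_ax[b] / g$step_z
    cx <- pars$x_app[b] / g$pixel_xy + cx0
    cy <- pars$y_app[b] / g$pixel_xy + cy0
    cz <- (pars$z[b] - g$z_centre) / g$step_z + cz0
    ix <- clip_range(cx, sx, g$nx)
    iy <- clip_range(cy, sx, g$ny)
    iz <- clip_range(cz, sz, g$nz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- norm_gauss(ix, cx, sx)
    gy <- norm_gauss(iy, cy, sx)
    gz <- norm_gauss(iz, cz, sz)
    arr[iy, ix, iz] <- arr[iy, ix, iz, drop = FALSE] +
      truth$flux * (gy %o% gx %o% gz)
  }
  if (isTRUE(noise$poisson) || noise$read_sigma > 0) {
    arr <- apply_camera_noise(arr, noise, seed)
  }
  bead_stack(arr, "straight", pixel_xy = g$pixel_xy, step_z = g$step_z,
             z_centre = g$z_centre)
}

# 0-based index range within +/- 4.5 sigma of centre c, clipped to [0, n-1],
# returned as 1-based R indices.
clip_range <- function(c0, sigma, n, nsig = 4.5) {
  lo <- max(0L, floor(c0 - nsig * sigma))
  hi <- min(n - 1L, ceiling(c0 + nsig * sigma))
  if (hi < lo) return(integer(0))
  seq.int(lo, hi) + 1L
}

# Unit-integral sampled Gaussian over 1-based indices idx (0-based coords).
norm_gauss <- function(idx, c0, sigma) {
  u <- (idx - 1) - c0
  exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

#' Oblique scan-series geometry
#'
#' @param n_steps Number of mirror steps (>= 3).
#' @param step_x Sample-space scan step along X per mirror step (um).
#' @param ny,n_obl Frame size in pixels (camera Y, oblique axis).
#' @param pixel_y,pixel_obl Sample-space pixel sizes (um).
#' @param tilt_deg Tilt of the imaged oblique plane (degrees).
#' @return A `scan_geometry` list.
#' @export
scan_geometry <- function(n_steps = 100, step_x = 1.4, ny = 64, n_obl = 64,
                          pixel_y = 0.25, pixel_obl = 0.25, tilt_deg = 28) {
  if (n_steps < 3) stop("scan series too short: need >= 3 steps", call. = FALSE)
  stopifnot(step_x > 0, ny >= 1, n_obl >= 1, pixel_y > 0, pixel_obl > 0,
            tilt_deg > 0, tilt_deg < 90)
  structure(list(n_steps = as.integer(n_steps), step_x = step_x,
                 ny = as.integer(ny), n_obl = as.integer(n_obl),
                 pixel_y = pixel_y, pixel_obl = pixel_obl,
                 tilt_deg = tilt_deg),
            class = "scan_geometry")
}

#' Render the noise-free oblique scan series of a bead scene
#'
#' Renders the tilted-plane scan of the bead field once, before illumination
#' and noise. Each frame samples the 3D scene on the oblique plane at one
#' mirror step; a bead's cartesian Gaussian becomes a correlated Gaussian in
#' (step, y, oblique) index coordinates under the shear map, which is rendered
#' exactly. The same base series can then be reused for many voltage ratios
#' via [apply_scan_illumination()], mirroring the experiment where one volume
#' is imaged repeatedly.
#'
#' @param truth A [scene_truth()].
#' @param geometry A [scan_geometry()].
#' @return An oblique-modality [bead_stack()] of expected counts (no noise,
#'   unit illumination).
#' @export
render_oblique_series <- function(truth, geometry) {
  g <- geometry
  th <- g$tilt_deg * pi / 180
  # index -> cartesian deltas, cartesian order (x, y, z)
  M <- rbind(c(g$step_x, 0, g$pixel_obl * cos(th)),
             c(0, g$pixel_y, 0),
             c(0, 0, g$pixel_obl * sin(th)))
  Minv <- solve(M)
  pars <- bead_render_params(truth)
  arr <- array(0, dim = c(g$ny, g$n_obl, g$n_steps))
  cs0 <- (g$n_steps - 1) / 2
  cy0 <- (g$ny - 1) / 2
  co0 <- (g$n_obl - 1) / 2
  for (b in seq_len(nrow(pars))) {
    Sigma <- diag(c(pars$sigma_lat[b]^2, pars$sigma_lat[b]^2,
                    pars$sigma_ax[b]^2))
    C <- Minv %*% Sigma %*% t(Minv)
    Q <- solve(C)
    sd_idx <- sqrt(diag(C))  # (step, y, obl)
    z <- pars$z[b]
    cs <- (pars$x_app[b] - z / tan(th)) / g$step_x + cs0
    cy <- pars$y_app[b] / g$pixel_y + cy0
    co <- z / (g$pixel_obl * sin(th)) + co0
    is_ <- clip_range(cs, sd_idx[1], g$n_steps)
    iy <- clip_range(cy, sd_idx[2], g$ny)
    io <- clip_range(co, sd_idx[3], g$n_obl)
    if (!length(is_) || !length(iy) || !length(io)) next
    d1 <- (is_ - 1) - cs
    d2 <- (iy - 1) - cy
    d3 <- (io - 1) - co
    ny_ <- length(iy); no_ <- length(io); ns_ <- length(is_)
    # rows iterate y fastest, then oblique, then step, matching [y, obl, step]
    grid <- cbind(rep(d1, each = ny_ * no_),
                  rep(d2, times = no_ * ns_),
                  rep(rep(d3, each = ny_), times = ns_))
    qf <- rowSums((grid %*% Q) * grid)
    val <- truth$flux * exp(-0.5 * qf) / ((2 * pi)^1.5 * sqrt(det(C)))
    arr[iy, io, is_] <- arr[iy, io, is_, drop = FALSE] +
      array(val, dim = c(ny_, no_, ns_))
  }
  bead_stack(arr, "oblique", pixel_y = g$pixel_y, pixel_obl = g$pixel_obl,
             scan_step = g$step_x, tilt_deg = g$tilt_deg)
}

#' Apply a scan illumination gradient and camera noise to a base series
#'
#' The illumination factor at step `s` (0-based) is
#' `1 + gradient_gain * (ratio - ratio_opt(objective_z)) * (s - (n-1)/2)`,
#' so a mirror-ratio mismatch tilts the summed intensity linearly across the
#' scan while a matched ratio leaves it flat.
#'
#' @param base An oblique [bead_stack()] from [render_oblique_series()].
#' @param truth The [scene_truth()] that produced it.
#' @param ratio Mirror voltage ratio used for this acquisition.
#' @param objective_z Primary objective Z position (mm).
#' @param noise A [noise_model()].
#' @param seed Seed for the noise draw.
#' @return An oblique [bead_stack()] with illumination and noise applied.
#' @export
apply_scan_illumination <- function(base, truth, ratio, objective_z = 0,
                                    noise = noise_model(), seed = NULL) {
  stopifnot(inherits(base, "bead_stack"), base$modality == "oblique")
  n <- dim(base$voxels)[3]
  mismatch <- ratio - truth_ratio_opt(truth, objective_z)
  fac <- 1 + truth$gradient_gain * mismatch * (seq_len(n) - 1 - (n - 1) / 2)
  if (any(fac < 0)) {
    warning("illumination factor negative at some steps; clamped to 0")
    fac <- pmax(fac, 0)
  }
  arr <- base$voxels * rep(fac, each = prod(dim(base$voxels)[1:2]))
  if (isTRUE(noise$poisson) || noise$read_sigma > 0) {
    arr <- apply_camera_noise(arr, noise, seed)
  }
  out <- base
  out$voxels <- arr
  out
}

#' Render an oblique scan series at a given mirror voltage ratio
#'
#' Convenience composition of [render_oblique_series()] and
#' [apply_scan_illumination()]. The expected normalized summed-intensity slope
#' of the result is `gradient_gain * (ratio - ratio_opt(objective_z))` per
#' step.
#'
#' @inheritParams apply_scan_illumination
#' @param truth A [scene_truth()].
#' @param geometry A [scan_geometry()].
#' @return An oblique-modality [bead_stack()].
#' @export
render_scan_series <- function(truth, ratio, objective_z = 0,
                               geometry = scan_geometry(),
                               noise = noise_model(), seed = NULL) {
  base <- render_oblique_series(truth, geometry)
  apply_scan_illumination(base, truth, ratio, objective_z, noise, seed)
}
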