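# Shear deskew: mapping oblique scan volumes (step, y, oblique-axis) onto a
# cartesian grid so the straight-path analysis applies unchanged.

#' Deskew specification
#'
#' Geometry of an oblique acquisition: tilt of the imaged plane, sample-space
#' scan step along X per mirror step, and pixel sizes along the oblique axis
#' and camera Y. The default 117 nm scan step gives square XY pixels in the
#' deskewed volume when `pixel_y` matches.
#'
#' @param tilt_deg Tilt of the light sheet / tertiary telescope (degrees,
#'   strictly between 0 and 90).
#' @param scan_step Scan step along X (um per mirror step).
#' @param pixel_obl Pixel size along the oblique axis (um).
#' @param pixel_y Pixel size along camera Y (um).
#' @param interpolation `"cubic"` (Catmull-Rom, default), `"linear"` or
#'   `"nearest"`. Cubic minimizes resampling broadening of near-Nyquist PSFs;
#'   nearest is count-preserving for QC.
#' @return A `deskew_spec` list.
#' @export
deskew_spec <- function(tilt_deg = 28, scan_step = 0.117, pixel_obl = 0.117,
                        pixel_y = 0.117,
                        interpolation = c("cubic", "linear", "nearest")) {
  if (tilt_deg <= 0 || tilt_deg >= 90) {
    stop("tilt_deg must lie in (0, 90)", call. = FALSE)
  }
  stopifnot(scan_step > 0, pixel_obl > 0, pixel_y > 0)
  structure(list(tilt_deg = tilt_deg, scan_step = scan_step,
                 pixel_obl = pixel_obl, pixel_y = pixel_y,
                 interpolation = match.arg(interpolation)),
            class = "deskew_spec")
}

#' Map oblique scan coordinates to cartesian sample coordinates
#'
#' The tilted imaging plane implies the shear map
#' `z = x_obl * pixel_obl * sin(tilt)`, `y = y_obl * pixel_y`,
#' `x = step * scan_step + x_obl * pixel_obl * cos(tilt)`,
#' with `(step, y_obl, x_obl)` in 0-based index units.
#'
#' @param p Numeric vector `c(step, y_obl, x_obl)` or a 3-column matrix.
#' @param spec A [deskew_spec()].
#' @return Cartesian `(x, y, z)` in um (vector or matrix matching `p`).
#' @export
oblique_to_cartesian <- function(p, spec) {
  th <- spec$tilt_deg * pi / 180
  m <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  out <- cbind(
    x = m[, 1] * spec$scan_step + m[, 3] * spec$pixel_obl * cos(th),
    y = m[, 2] * spec$pixel_y,
    z = m[, 3] * spec$pixel_obl * sin(th)
  )
  if (is.matrix(p)) out else drop(out)
}

#' Deskew an oblique scan volume to cartesian coordinates
#'
#' Resamples the raw `[y, oblique, step]` volume onto a cartesian `[y, x, z]`
#' grid via the inverse of [oblique_to_cartesian()]. The output grid is chosen
#' so that only the scan (step) axis needs interpolation: the Z voxel equals
#' `pixel_obl * sin(tilt)` (each oblique index is one Z plane), Y is carried
#' over unchanged, and the X voxel equals `scan_step`. Intensity is
#' interpolated, not integrated; voxels falling outside the acquired sheared
#' footprint are zero.
#'
#' @param raw An oblique-modality [bead_stack()].
#' @param spec A [deskew_spec()]; defaults are taken from the stack metadata.
#' @return A straight-modality [bead_stack()] with `pixel_xy = scan_step`
#'   (requires `pixel_y == scan_step` for exactly square XY pixels; a
#'   mismatch is an error) and `step_z = pixel_obl * sin(tilt)`.
#' @export
deskew_volume <- function(raw, spec = NULL) {
  stopifnot(inherits(raw, "bead_stack"))
  if (raw$modality != "oblique") {
    stop("deskew_volume expects an oblique stack", call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- deskew_spec(tilt_deg = raw$tilt_deg, scan_step = raw$scan_step,
                        pixel_obl = raw$pixel_obl, pixel_y = raw$pixel_y)
  }
  if (abs(spec$tilt_deg - raw$tilt_deg) > 1e-9 ||
      abs(spec$scan_step - raw$scan_step) > 1e-9 ||
      abs(spec$pixel_obl - raw$pixel_obl) > 1e-9 ||
      abs(spec$pixel_y - raw$pixel_y) > 1e-9) {
    stop("deskew_spec does not match the stack metadata", call. = FALSE)
  }
  if (abs(spec$pixel_y - spec$scan_step) > 1e-9) {
    stop("non-square output pixels: pixel_y must equal scan_step",
         call. = FALSE)
  }
  th <- spec$tilt_deg * pi / 180
  d <- dim(raw$voxels)
  ny <- d[1]; n_obl <- d[2]; n_steps <- d[3]
  shear_per_obl <- spec$pixel_obl * cos(th) / spec$scan_step
  n_x <- n_steps + ceiling((n_obl - 1) * shear_per_obl)
  out <- array(0, dim = c(ny, n_x, n_obl))
  ix <- seq_len(n_x) - 1
  for (iz in seq_len(n_obl) - 1) {
    plane <- raw$voxels[, iz + 1, ]          # [y, step]
    off <- iz * shear_per_obl                # step position = ix - off
    m <- floor(off)
    t <- off - m
    out[, , iz + 1] <- shift_interp(plane, ix - m, t, spec$interpolation)
  }
  out <- pmax(out, 0)
  bead_stack(out, "straight", pixel_xy = spec$scan_step,
             step_z = spec$pixel_obl * sin(th),
             z_centre = (n_obl - 1) / 2 * spec$pixel_obl * sin(th))
}

# Sample the columns (step axis) of plane [y, step] at positions k - t for
# integer targets k (0-based) and constant fractional phase t in [0, 1).
# Out-of-range taps contribute zero.
shift_interp <- function(plane, k, t, method) {
  n <- ncol(plane)
  col_at <- function(j) {
    # j: 0-based step indices, vectorized; zero outside [0, n-1]
    inside <- j >= 0 & j <= n - 1
    res <- matrix(0, nrow(plane), length(j))
    res[, inside] <- plane[, j[inside] + 1, drop = FALSE]
    res
  }
  if (method == "nearest" || t == 0) {
    j <- if (t < 0.5) k else k - 1  # nearest integer to k - t
    if (t == 0) j <- k
    return(col_at(j))
  }
  if (method == "linear") {
    # position p = k - t lies between k - 1 and k
    return(t * col_at(k - 1) + (1 - t) * col_at(k))
  }
  # Catmull-Rom cubic on taps (k-2, k-1, k, k+1) with local phase u = 1 - t
  u <- 1 - t
  w_m1 <- -0.5 * u + u^2 - 0.5 * u^3
  w_0 <- 1 - 2.5 * u^2 + 1.5 * u^3
  w_p1 <- 0.5 * u + 2 * u^2 - 1.5 * u^3
  w_p2 <- -0.5 * u^2 + 0.5 * u^3
  w_m1 * col_at(k - 2) + w_0 * col_at(k - 1) + w_p1 * col_at(k) +
    w_p2 * col_at(k + 1)
}
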