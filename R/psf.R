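# Bead PSF measurement: focus selection, wavelet spot detection, and the
# 2D/1D Gaussian fit cascade producing per-bead FWHM records.

#' Variance-of-Laplacian focus metric
#'
#' Pech-Pacheco's LAPV autofocus measure: the variance of the discrete
#' 4-neighbour Laplacian of the image. Higher means sharper; a constant image
#' scores 0, and the metric is invariant to adding a constant offset.
#'
#' @param image 2D numeric matrix (at least 2x2).
#' @return Non-negative scalar.
#' @export
focus_metric <- function(image) {
  stopifnot(is.matrix(image), nrow(image) >= 2, ncol(image) >= 2)
  lap <- laplacian4(image)
  stats::var(as.vector(lap))
}

# Discrete 4-neighbour Laplacian with replicated edges.
laplacian4 <- function(m) {
  up <- m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nrow(m))[-1], nrow(m)), , drop = FALSE]
  lf <- m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
  rt <- m[, c(seq_len(ncol(m))[-1], ncol(m)), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

#' Frame with the best overall focus
#'
#' Argmax of [focus_metric()] over the planes of a stack; exact ties are
#' broken toward the stack centre.
#'
#' @param stack A straight-modality [bead_stack()] (or a 3D array).
#' @return 1-based frame index.
#' @export
best_focus_frame <- function(stack) {
  arr <- if (inherits(stack, "bead_stack")) stack$voxels else stack
  stopifnot(is.array(arr), length(dim(arr)) == 3, dim(arr)[3] >= 1)
  scores <- vapply(seq_len(dim(arr)[3]),
                   function(k) focus_metric(arr[, , k]), numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1) {
    centre <- (dim(arr)[3] + 1) / 2
    best <- best[which.min(abs(best - centre))]
  }
  best
}

#' A-trous B3-spline wavelet planes of an image
#'
#' Undecimated (a-trous) wavelet transform with the B3-spline scaling kernel
#' (1, 4, 6, 4, 1)/16, applied separably with the holes doubling at each
#' scale; wavelet plane j is the difference between successive smoothed
#' approximations. Edges are handled by replication.
#'
#' @param image 2D numeric matrix.
#' @param n_scales Number of wavelet planes to compute.
#' @return List of matrices `W1..Wn` plus the final approximation `A`.
#' @export
atrous_planes <- function(image, n_scales = 3) {
  stopifnot(is.matrix(image), n_scales >= 1)
  planes <- vector("list", n_scales)
  approx <- image
  for (j in seq_len(n_scales)) {
    sm <- b3_smooth(approx, spacing = 2^(j - 1))
    planes[[j]] <- approx - sm
    approx <- sm
  }
  names(planes) <- paste0("W", seq_len(n_scales))
  c(planes, list(A = approx))
}

# Separable B3-spline smoothing with taps at +/- spacing and +/- 2*spacing,
# replicated edges.
b3_smooth <- function(m, spacing) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2, -1, 0, 1, 2) * spacing
  conv1 <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    out <- 0
    for (i in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[i], 1L), n)
      out <- out + w[i] * (if (along_rows) x[idx, , drop = FALSE]
                           else x[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Detect bead candidates by a-trous wavelet thresholding
#'
#' Thresholds one wavelet plane (default the second, which responds to
#' diffraction-limited spots) at `k` robust standard deviations (`k * mad` of
#' the plane), labels connected components, discards components smaller than
#' `min_area` pixels, and returns intensity-weighted centroids deduplicated
#' within a minimum separation (brightest kept). On a sparse noise-free image
#' the plane's `mad` can collapse to zero; a floor of `noise_floor * max(W)`
#' guards the threshold there.
#'
#' @param image 2D matrix (typically the best-focus frame).
#' @param k Threshold in robust sigmas of the wavelet plane.
#' @param plane Wavelet plane used for detection.
#' @param min_area Minimum component area in pixels. The default 12 sits
#'   between the largest clusters pure read noise produces at `k = 3`
#'   (single-digit areas) and the ~20+ pixel components of a
#'   diffraction-limited bead at usable SNR.
#' @param min_separation Minimum candidate separation in pixels.
#' @param noise_floor Threshold floor as a fraction of the plane maximum.
#' @return Data frame with 0-based pixel coordinates `x`, `y` and the
#'   component weight `mass` (possibly 0 rows).
#' @export
detect_beads <- function(image, k = 3, plane = 2, min_area = 12,
                         min_separation = 4, noise_floor = 0.02) {
  pl <- atrous_planes(image, n_scales = plane)[[paste0("W", plane)]]
  thr <- max(k * stats::mad(pl), noise_floor * max(pl), 0)
  mask <- pl > thr
  if (!any(mask)) return(empty_candidates())
  lab <- EBImage::bwlabel(mask)
  labv <- as.vector(lab)
  keep <- labv > 0
  if (!any(keep)) return(empty_candidates())
  id <- labv[keep]
  wgt <- as.vector(pl)[keep]
  wgt[wgt < 0] <- 0
  ij <- arrayInd(which(keep), dim(pl))
  area <- tabulate(id)
  mass <- vapply(split(wgt, id), sum, numeric(1))
  cy <- vapply(split(wgt * ij[, 1], id), sum, numeric(1)) / mass
  cx <- vapply(split(wgt * ij[, 2], id), sum, numeric(1)) / mass
  ok <- area >= min_area & mass > 0
  if (!any(ok)) return(empty_candidates())
  cand <- data.frame(x = cx[ok] - 1, y = cy[ok] - 1, mass = mass[ok])
  dedup_candidates(cand, min_separation)
}

empty_candidates <- function() {
  data.frame(x = numeric(0), y = numeric(0), mass = numeric(0))
}

# Greedy dedup: keep the heaviest candidate of any pair closer than min_sep.
dedup_candidates <- function(cand, min_sep) {
  cand <- cand[order(-cand$mass), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an elliptical 2D Gaussian to one bead
#'
#' Least-squares fit of an axis-aligned elliptical Gaussian plus constant
#' background over a square region of interest. The fit is flagged not-OK when
#' the ROI is clipped by the image border, the optimizer fails or hits its
#' bounds, R-squared falls below `r2_min`, or the fitted centre leaves the
#' ROI.
#'
#' @param image 2D matrix.
#' @param candidate Numeric `c(x, y)`, 0-based pixel coordinates.
#' @param roi_halfwidth ROI half-width in pixels.
#' @param r2_min Minimum R-squared for a usable fit.
#' @return One-row data frame: `x`, `y` (0-based pixels, sub-pixel),
#'   `sigma_x`, `sigma_y`, `fwhm_x`, `fwhm_y` (pixels), `amplitude`,
#'   `background` (counts), `r2`, `fit_ok`.
#' @export
fit_bead_2d <- function(image, candidate, roi_halfwidth = 5, r2_min = 0.8) {
  hw <- roi_halfwidth
  cx <- round(candidate[1]) ; cy <- round(candidate[2])
  bad <- data.frame(x = NA_real_, y = NA_real_, sigma_x = NA_real_,
                    sigma_y = NA_real_, fwhm_x = NA_real_, fwhm_y = NA_real_,
                    amplitude = NA_real_, background = NA_real_,
                    r2 = NA_real_, fit_ok = FALSE)
  # 0-based bounds check against the image border
  if (cx - hw < 0 || cy - hw < 0 ||
      cx + hw > ncol(image) - 1 || cy + hw > nrow(image) - 1) {
    return(bad)
  }
  xi <- (cx - hw):(cx + hw)
  yi <- (cy - hw):(cy + hw)
  roi <- image[yi + 1, xi + 1]
  df <- data.frame(x = rep(xi, each = length(yi)),
                   y = rep(yi, times = length(xi)),
                   v = as.vector(roi))
  bg0 <- min(roi)
  amp0 <- max(roi) - bg0
  if (amp0 <= 0) return(bad)
  start <- list(A = amp0, x0 = candidate[1], y0 = candidate[2],
                sx = 1.2, sy = 1.2, B = bg0)
  lower <- c(A = 0, x0 = cx - hw, y0 = cy - hw, sx = 0.25, sy = 0.25, B = -Inf)
  upper <- c(A = Inf, x0 = cx + hw, y0 = cy + hw, sx = 2 * hw, sy = 2 * hw,
             B = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ B + A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((df$v - mean(df$v))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  at_bound <- p["sx"] <= 0.2501 || p["sy"] <= 0.2501 ||
    p["sx"] >= 2 * hw - 1e-6 || p["sy"] >= 2 * hw - 1e-6
  in_roi <- p["x0"] > cx - hw && p["x0"] < cx + hw &&
    p["y0"] > cy - hw && p["y0"] < cy + hw
  ok <- is.finite(r2) && r2 >= r2_min && !at_bound && in_roi && p["A"] > 0
  data.frame(x = unname(p["x0"]), y = unname(p["y0"]),
             sigma_x = unname(p["sx"]), sigma_y = unname(p["sy"]),
             fwhm_x = FWHM_SIGMA * unname(p["sx"]),
             fwhm_y = FWHM_SIGMA * unname(p["sy"]),
             amplitude = unname(p["A"]), background = unname(p["B"]),
             r2 = r2, fit_ok = ok)
}

# Bilinear sub-pixel sample of every frame at 0-based (x, y).
sample_profile <- function(arr, x, y) {
  x1 <- floor(x); y1 <- floor(y)
  fx <- x - x1; fy <- y - y1
  nx <- dim(arr)[2]; ny <- dim(arr)[1]
  x1 <- min(max(x1, 0), nx - 2); y1 <- min(max(y1, 0), ny - 2)
  v11 <- arr[y1 + 1, x1 + 1, ]
  v12 <- arr[y1 + 1, x1 + 2, ]
  v21 <- arr[y1 + 2, x1 + 1, ]
  v22 <- arr[y1 + 2, x1 + 2, ]
  (1 - fy) * ((1 - fx) * v11 + fx * v12) + fy * ((1 - fx) * v21 + fx * v22)
}

#' Fit the axial intensity profile of one bead
#'
#' Extracts the intensity at a fixed (sub-pixel, bilinear) lateral position
#' across all frames of the stack and fits a 1D Gaussian plus offset. Profiles
#' peaking within `edge_frames` of the stack boundary are flagged.
#'
#' @param stack A straight-modality [bead_stack()].
#' @param x,y 0-based pixel coordinates of the bead (from [fit_bead_2d()]).
#' @param edge_frames Frames from the boundary within which a peak is flagged.
#' @param r2_min Minimum R-squared for a usable fit.
#' @return One-row data frame: `z_best` (um, absolute depth), `z_frame`
#'   (1-based frame of best focus), `fwhm_z` (nm), `r2`, `fit_ok`.
#' @export
fit_axial_profile <- function(stack, x, y, edge_frames = 2, r2_min = 0.8) {
  arr <- stack$voxels
  nz <- dim(arr)[3]
  prof <- sample_profile(arr, x, y)
  df <- data.frame(k = seq_len(nz) - 1, v = prof)
  bad <- data.frame(z_best = NA_real_, z_frame = NA_integer_,
                    fwhm_z = NA_real_, r2 = NA_real_, fit_ok = FALSE)
  k0 <- which.max(prof) - 1
  bg0 <- min(prof)
  amp0 <- max(prof) - bg0
  if (amp0 <= 0) return(bad)
  sz0 <- max(1, 0.3 / stack$step_z / FWHM_SIGMA * 0.7)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ B + A * exp(-(k - k0f)^2 / (2 * sz^2)),
                      data = df,
                      start = list(A = amp0, k0f = k0, sz = sz0, B = bg0),
                      lower = c(A = 0, k0f = 0, sz = 0.25, B = -Inf),
                      upper = c(A = Inf, k0f = nz - 1, sz = nz, B = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((df$v - mean(df$v))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  at_edge <- p["k0f"] < edge_frames || p["k0f"] > nz - 1 - edge_frames
  ok <- is.finite(r2) && r2 >= r2_min && !at_edge && p["A"] > 0 &&
    p["sz"] < nz / 2
  z_best <- stack$z_centre + (unname(p["k0f"]) - (nz - 1) / 2) * stack$step_z
  data.frame(z_best = z_best,
             z_frame = as.integer(round(unname(p["k0f"]))) + 1L,
             fwhm_z = 1000 * FWHM_SIGMA * unname(p["sz"]) * stack$step_z,
             r2 = r2, fit_ok = ok)
}

#' Measure the PSF of every bead in a stack
#'
#' The full bead-analysis cascade: pick the globally best-focused frame,
#' detect candidate beads on it with the a-trous wavelet detector, fit each
#' with a provisional 2D Gaussian, extract and fit the axial profile at the
#' fitted lateral position, then refit the 2D Gaussian at each bead's own best
#' focal plane. Records failing any stage are flagged rather than dropped.
#'
#' @param stack A straight-modality [bead_stack()].
#' @param roi_halfwidth ROI half-width for the lateral fits (pixels).
#' @param detect_args Named list of overrides for [detect_beads()].
#' @return Data frame of bead records: positions `x`, `y` (um from the image
#'   centre), `z_best` (um), FWHMs `fwhm_x`, `fwhm_y`, `fwhm_lat`, `fwhm_z`
#'   (nm), `amplitude`, `background`, polar coordinates `r` (um) and `theta`
#'   (radians in (-pi, pi]), and `fit_ok`.
#' @export
measure_psfs <- function(stack, roi_halfwidth = 5, detect_args = list()) {
  stopifnot(inherits(stack, "bead_stack"), stack$modality == "straight")
  arr <- stack$voxels
  nx <- dim(arr)[2]; ny <- dim(arr)[1]
  kbest <- best_focus_frame(stack)
  cand <- do.call(detect_beads, c(list(image = arr[, , kbest]), detect_args))
  if (nrow(cand) == 0) return(empty_bead_records())
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f1 <- fit_bead_2d(arr[, , kbest], c(cand$x[i], cand$y[i]), roi_halfwidth)
    if (!isTRUE(f1$fit_ok)) {
      rows[[i]] <- bead_record_row(f1, ax = NULL, stack, nx, ny)
      next
    }
    ax <- fit_axial_profile(stack, f1$x, f1$y)
    f2 <- f1
    if (isTRUE(ax$fit_ok) && ax$z_frame != kbest) {
      f2b <- fit_bead_2d(arr[, , ax$z_frame], c(f1$x, f1$y), roi_halfwidth)
      if (isTRUE(f2b$fit_ok)) f2 <- f2b
    }
    rows[[i]] <- bead_record_row(f2, ax, stack, nx, ny)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_bead_records <- function() {
  data.frame(x = numeric(0), y = numeric(0), z_best = numeric(0),
             fwhm_x = numeric(0), fwhm_y = numeric(0), fwhm_lat = numeric(0),
             fwhm_z = numeric(0), amplitude = numeric(0),
             background = numeric(0), r = numeric(0), theta = numeric(0),
             fit_ok = logical(0))
}

bead_record_row <- function(fit2d, ax, stack, nx, ny) {
  px <- stack$pixel_xy
  x_um <- (fit2d$x - (nx - 1) / 2) * px
  y_um <- (fit2d$y - (ny - 1) / 2) * px
  theta <- atan2(y_um, x_um)
  if (!is.na(theta) && theta <= -pi) theta <- pi
  data.frame(
    x = x_um, y = y_um,
    z_best = if (is.null(ax)) NA_real_ else ax$z_best,
    fwhm_x = 1000 * px * fit2d$fwhm_x,
    fwhm_y = 1000 * px * fit2d$fwhm_y,
    fwhm_lat = 1000 * px * (fit2d$fwhm_x + fit2d$fwhm_y) / 2,
    fwhm_z = if (is.null(ax)) NA_real_ else ax$fwhm_z,
    amplitude = fit2d$amplitude, background = fit2d$background,
    r = sqrt(x_um^2 + y_um^2), theta = theta,
    fit_ok = isTRUE(fit2d$fit_ok) && !is.null(ax) && isTRUE(ax$fit_ok)
  )
}

#' Summarize bead FWHMs by radial distance
#'
#' Bins usable bead records by radial distance from the image centre and
#' reports per-bin mean, standard deviation and count of the lateral (x/y
#' mean) and axial FWHM. Bins with fewer than `min_count` beads are omitted.
#'
#' @param records Bead records from [measure_psfs()].
#' @param bin_edges Radial bin edges in um (increasing).
#' @param depth_label Optional label (e.g. the sample depth) copied to the
#'   output.
#' @param min_count Minimum beads per reported bin.
#' @return Data frame with one row per occupied bin: `r_mid`, `n`,
#'   `fwhm_lat_mean`, `fwhm_lat_sd`, `fwhm_z_mean`, `fwhm_z_sd`, `depth`.
#' @export
summarize_by_radius <- function(records, bin_edges, depth_label = NA,
                                min_count = 3) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  rec <- records[records$fit_ok & !is.na(records$fwhm_z), , drop = FALSE]
  if (nrow(rec) == 0) {
    return(data.frame(r_mid = numeric(0), n = integer(0),
                      fwhm_lat_mean = numeric(0), fwhm_lat_sd = numeric(0),
                      fwhm_z_mean = numeric(0), fwhm_z_sd = numeric(0),
                      depth = numeric(0)))
  }
  bin <- cut(rec$r, breaks = bin_edges, include.lowest = TRUE)
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  out <- do.call(rbind, lapply(seq_along(levels(bin)), function(i) {
    sel <- !is.na(bin) & bin == levels(bin)[i]
    n <- sum(sel)
    if (n < min_count) return(NULL)
    data.frame(r_mid = mids[i], n = n,
               fwhm_lat_mean = mean(rec$fwhm_lat[sel]),
               fwhm_lat_sd = stats::sd(rec$fwhm_lat[sel]),
               fwhm_z_mean = mean(rec$fwhm_z[sel]),
               fwhm_z_sd = stats::sd(rec$fwhm_z[sel]),
               depth = depth_label)
  }))
  if (is.null(out)) out <- summarize_by_radius(rec[0, ], bin_edges)
  rownames(out) <- NULL
  out
}
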