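# Two-galvo scan voltage-ratio calibration: summed-intensity slopes per
# ratio, the zero-slope (optimal) ratio per objective position, and the
# linear calibration curve ratio_opt(objective_z).

#' Normalized summed-intensity series of an oblique scan
#'
#' Sums all pixels of every frame and divides by the mean over steps, so the
#' output averages exactly 1. A mirror-ratio mismatch shows up as a linear
#' trend of these values against step number.
#'
#' @param series An oblique [bead_stack()] (or 3D array `[y, obl, step]`).
#' @param subtract_offset Optional constant camera offset (counts per pixel)
#'   subtracted from every frame sum before normalization; 0 (none) by
#'   default. A nonzero dark level attenuates normalized slopes.
#' @return Numeric vector of length `n_steps`, mean exactly 1. All-zero
#'   frames trigger a warning (the normalization is still defined as long as
#'   the series mean is positive).
#' @export
summed_intensity_series <- function(series, subtract_offset = 0) {
  arr <- if (inherits(series, "bead_stack")) series$voxels else series
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  n <- dim(arr)[3]
  if (n < 3) stop("scan series too short: need >= 3 steps", call. = FALSE)
  sums <- apply(arr, 3, sum) - subtract_offset * prod(dim(arr)[1:2])
  if (any(sums == 0)) warning("all-zero frame(s) in scan series")
  m <- mean(sums)
  if (m <= 0) stop("non-positive mean summed intensity", call. = FALSE)
  sums / m
}

#' Slope of a normalized intensity series
#'
#' Ordinary least-squares slope of the normalized summed-intensity values
#' against the 0-based step index.
#'
#' @param values Normalized values from [summed_intensity_series()].
#' @return List with `slope` (per step), `stderr`, `n`.
#' @export
slope_for_ratio <- function(values) {
  n <- length(values)
  if (n < 3) stop("need >= 3 points for a slope", call. = FALSE)
  step <- seq_len(n) - 1
  sxx <- sum((step - mean(step))^2)
  slope <- sum((step - mean(step)) * (values - mean(values))) / sxx
  res <- values - mean(values) - slope * (step - mean(step))
  list(slope = slope, stderr = sqrt(sum(res^2) / (n - 2) / sxx), n = n)
}

#' Optimal mirror voltage ratio from a slope sweep
#'
#' Fits the measured slopes against the voltage ratios with a straight line
#' (the slope-vs-ratio relation is taken as linear) and returns the ratio at
#' which the fitted line crosses zero -- the ratio that places the scan pivot
#' at the objective pupil. The crossing uncertainty is propagated from the
#' fit covariance by the delta method. A crossing outside the swept range is
#' returned with a warning.
#'
#' @param ratios Voltage ratios (>= 2 distinct, > 0).
#' @param slopes Measured normalized-intensity slopes, one per ratio.
#' @param objective_z Objective Z position (mm), carried to the output.
#' @return An object of class `ratio_sweep_result`: list with `objective_z`,
#'   `entries` (data frame ratio/slope), `ratio_opt`, `crossing_stderr`,
#'   `gain` (fitted d slope / d ratio), `extrapolated`.
#' @export
optimal_ratio <- function(ratios, slopes, objective_z = NA_real_) {
  stopifnot(length(ratios) == length(slopes))
  if (length(unique(ratios)) < 2) {
    stop("need >= 2 distinct ratios", call. = FALSE)
  }
  if (any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  fit <- ols_line(ratios, slopes)
  scale <- max(abs(slopes), .Machine$double.eps)
  if (abs(fit$b) < 1e-10 * scale / diff(range(ratios))) {
    stop("no zero crossing: slope-vs-ratio line is flat", call. = FALSE)
  }
  r0 <- -fit$a / fit$b
  grad <- c(-1 / fit$b, fit$a / fit$b^2)
  se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  extrap <- r0 < min(ratios) || r0 > max(ratios)
  if (extrap) {
    warning("optimal ratio extrapolates beyond the swept ratios")
  }
  structure(list(objective_z = objective_z,
                 entries = data.frame(ratio = ratios, slope = slopes),
                 ratio_opt = r0, crossing_stderr = se,
                 gain = fit$b, extrapolated = extrap),
            class = "ratio_sweep_result")
}

#' Measure one voltage-ratio sweep at a fixed objective position
#'
#' Convenience wrapper: for each acquired series, computes the normalized
#' summed-intensity series and its slope, then locates the zero-slope ratio.
#'
#' @param series_list List of oblique [bead_stack()] series, one per ratio.
#' @param ratios Voltage ratios matching `series_list`.
#' @param objective_z Objective Z position (mm).
#' @param subtract_offset Passed to [summed_intensity_series()].
#' @return A `ratio_sweep_result` (see [optimal_ratio()]) whose `entries`
#'   also carry the per-ratio slope standard errors.
#' @export
measure_ratio_sweep <- function(series_list, ratios, objective_z = NA_real_,
                                subtract_offset = 0) {
  stopifnot(length(series_list) == length(ratios))
  fits <- lapply(series_list, function(s) {
    slope_for_ratio(summed_intensity_series(s, subtract_offset))
  })
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  res <- optimal_ratio(ratios, slopes, objective_z)
  res$entries$slope_stderr <- vapply(fits, `[[`, numeric(1), "stderr")
  res
}

#' Mirror voltage-ratio calibration curve
#'
#' Ordinary least-squares line through the per-position optimal ratios:
#' `ratio_opt(z) = a + b * z`. The fitted curve is what the acquisition
#' software evaluates on the fly as the user moves the focus.
#'
#' @param objective_z Objective Z positions (mm, >= 2 distinct).
#' @param ratio_opt Optimal ratios at those positions.
#' @return An object of class `calibration_curve`: list with `a`, `b`,
#'   `a_stderr`, `b_stderr`, `residuals`, `points`.
#' @export
calibration_curve <- function(objective_z, ratio_opt) {
  stopifnot(length(objective_z) == length(ratio_opt))
  if (length(unique(objective_z)) < 2) {
    stop("need >= 2 distinct objective positions", call. = FALSE)
  }
  fit <- ols_line(objective_z, ratio_opt)
  structure(list(a = fit$a, b = fit$b,
                 a_stderr = fit$a_stderr, b_stderr = fit$b_stderr,
                 residuals = fit$residuals,
                 points = data.frame(objective_z = objective_z,
                                     ratio_opt = ratio_opt)),
            class = "calibration_curve")
}

#' Predict the optimal mirror voltage ratio at an objective position
#'
#' @param object A [calibration_curve()].
#' @param z Objective Z position(s) in mm.
#' @param ... Unused.
#' @return Predicted optimal ratio(s) `a + b * z`.
#' @export
predict.calibration_curve <- function(object, z, ...) {
  object$a + object$b * z
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: ratio_opt(z) = %.6f + %.6f * z (z in mm)\n",
              x$a, x$b))
  cat(sprintf("  fitted over %d positions, residual sd %.2e\n",
              nrow(x$points), stats::sd(x$residuals)))
  invisible(x)
}
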