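# TIFF + YAML sidecar I/O for bead stacks. Stacks are written as multi-page
# 16-bit TIFFs (ImageJ-style plane order) with counts rescaled to the 16-bit
# range; the scale factor and all voxel/modality metadata travel in a YAML
# sidecar next to the image file.

#' Write a bead stack as a multi-page TIFF with a YAML sidecar
#'
#' @param stack A [bead_stack()].
#' @param path Output TIFF path; the sidecar is written to `<path>.yaml`.
#' @param truth Optional [scene_truth()] whose injected parameters (flux, PSF
#'   field, distortion rate, ratio map, gradient gain, seed) are recorded in
#'   the sidecar for downstream recovery tests.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "bead_stack"))
  arr <- stack$voxels
  scale <- max(arr)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(k) arr[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(
    modality = stack$modality,
    dim = as.integer(dim(arr)),
    max_counts = scale,
    pixel_xy = stack$pixel_xy, step_z = stack$step_z,
    z_centre = stack$z_centre,
    pixel_y = stack$pixel_y, pixel_obl = stack$pixel_obl,
    scan_step = stack$scan_step, tilt_deg = stack$tilt_deg
  )
  if (!is.null(truth)) {
    meta$truth <- list(
      flux = truth$flux,
      psf_model = unclass(truth$psf_model),
      distortion_rate = truth$distortion_rate,
      ratio_opt_map = as.list(truth$ratio_opt_map),
      gradient_gain = truth$gradient_gain,
      fov = truth$fov, seed = truth$seed,
      positions = list(x = truth$positions$x, y = truth$positions$y,
                       z = truth$positions$z)
    )
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a bead stack written by [write_stack_tiff()]
#'
#' @param path TIFF path with a `<path>.yaml` sidecar alongside.
#' @return A [bead_stack()]; counts are restored from the recorded scale (up
#'   to 16-bit quantization).
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = meta$dim)
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$max_counts
  if (meta$modality == "straight") {
    bead_stack(arr, "straight", pixel_xy = meta$pixel_xy,
               step_z = meta$step_z, z_centre = meta$z_centre)
  } else {
    bead_stack(arr, "oblique", pixel_y = meta$pixel_y,
               pixel_obl = meta$pixel_obl, scan_step = meta$scan_step,
               tilt_deg = meta$tilt_deg)
  }
}

#' Read the scene truth recorded in a stack sidecar
#'
#' @param path TIFF path whose sidecar carries a `truth` block.
#' @return The reconstructed [scene_truth()].
#' @export
read_truth_sidecar <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  if (is.null(meta$truth)) stop("sidecar has no truth block", call. = FALSE)
  tr <- meta$truth
  scene_truth(
    positions = data.frame(x = unlist(tr$positions$x),
                           y = unlist(tr$positions$y),
                           z = unlist(tr$positions$z)),
    flux = tr$flux,
    psf_model = do.call(psf_field_model, tr$psf_model),
    distortion_rate = tr$distortion_rate,
    ratio_opt_map = c(a = tr$ratio_opt_map$a, b = tr$ratio_opt_map$b),
    gradient_gain = tr$gradient_gain,
    fov = if (is.null(tr$fov)) NULL else unlist(tr$fov),
    seed = if (is.null(tr$seed)) NA_integer_ else tr$seed
  )
}
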