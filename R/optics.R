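#' Optical configuration of the remote-focusing train
#'
#' Bundles the first-order parameters of an OPM remote-focusing train:
#' primary objective and tube lens, remote (second) objective and tube lens,
#' immersion refractive indices, and the tilt of the tertiary telescope.
#' Defaults describe a 100X/1.35 NA silicone-oil primary (n = 1.406) on a
#' 180 mm tube-lens base, relayed into a 40X air remote objective through a
#' 321 mm tube-lens assembly, with the tertiary path tilted at 28 degrees.
#'
#' @param f_tl1 Focal length of the primary tube lens (mm).
#' @param M1_nominal Nominal magnification of the primary objective.
#' @param M2_nominal Nominal magnification of the remote objective.
#' @param f_design Tube-lens focal-length standard both objectives are
#'   specified against (mm); 180 mm for Olympus optics. The objective focal
#'   length is `f_design / M_nominal`.
#' @param n1 Refractive index of the primary immersion medium.
#' @param n2 Refractive index of the remote immersion medium.
#' @param f_tl2 Focal length of the remote tube lens actually installed (mm).
#' @param tilt_deg Tilt of the tertiary telescope relative to the remote
#'   objective axis (degrees), strictly between 0 and 90.
#'
#' @return An object of class `optical_config` (a named list).
#' @export
optical_config <- function(f_tl1 = 180, M1_nominal = 100, M2_nominal = 40,
                           f_design = 180, n1 = 1.406, n2 = 1.0,
                           f_tl2 = 321, tilt_deg = 28) {
  cfg <- list(f_tl1 = f_tl1, M1_nominal = M1_nominal, M2_nominal = M2_nominal,
              f_design = f_design, n1 = n1, n2 = n2, f_tl2 = f_tl2,
              tilt_deg = tilt_deg)
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("invalid optical_config: all parameters must be finite scalars",
         call. = FALSE)
  }
  pos <- c("f_tl1", "M1_nominal", "M2_nominal", "f_design", "f_tl2")
  if (any(vapply(cfg[pos], `<=`, logical(1), 0))) {
    stop("invalid optical_config: focal lengths and magnifications must be > 0",
         call. = FALSE)
  }
  if (cfg$n1 < 1 || cfg$n2 < 1) {
    stop("invalid optical_config: refractive indices must be >= 1",
         call. = FALSE)
  }
  if (cfg$tilt_deg <= 0 || cfg$tilt_deg >= 90) {
    stop("invalid optical_config: tilt_deg must lie in (0, 90)", call. = FALSE)
  }
  structure(cfg, class = "optical_config")
}

as_optical_config <- function(cfg) {
  if (inherits(cfg, "optical_config")) return(cfg)
  if (is.list(cfg)) return(do.call(optical_config, cfg))
  stop("expected an optical_config", call. = FALSE)
}

#' Ideal remote tube-lens focal length
#'
#' Aberration-free remote focusing requires the overall magnification between
#' the primary-objective space and the remote-objective space to equal the
#' ratio of the immersion refractive indices, n1/n2. With objective focal
#' lengths f_obj = f_design / M_nominal, the magnification of the relay is
#' (f_tl1 / f_obj1) * (f_obj2 / f_tl2) and the condition solves to
#'
#'   f_tl2* = M1 * (f_design / M2) * n2 / n1.
#'
#' The exact solution is returned (320.06 mm for the default train); rounding
#' to a catalogue value is left to the caller.
#'
#' @param cfg An [optical_config()].
#' @return Ideal remote tube-lens focal length in mm.
#' @export
#' @examples
#' remote_tube_lens_focal(optical_config()) # 320.06 mm
remote_tube_lens_focal <- function(cfg) {
  cfg <- as_optical_config(cfg)
  cfg$M1_nominal * (cfg$f_design / cfg$M2_nominal) * cfg$n2 / cfg$n1
}

#' Convert a lateral extent at the primary image plane to sample space
#'
#' Lateral distances demagnify by the lateral magnification M, so a 20 mm
#' image-plane field maps to 200 um at the sample for a 100X system.
#'
#' @param extent Lateral extent at the image plane (any length unit).
#' @param M Lateral magnification (> 0).
#' @return Extent in sample space, same unit as `extent`.
#' @export
lateral_image_to_sample <- function(extent, M) {
  if (!is.numeric(M) || any(M <= 0)) {
    stop("invalid magnification: M must be > 0", call. = FALSE)
  }
  extent / M
}

#' Convert an axial shift at the primary image plane to sample space
#'
#' Axial (longitudinal) distances demagnify by the square of the lateral
#' magnification: a 0.92 mm focal-plane shift at the image plane of a 100X
#' system is 92 nm of focal shift at the sample.
#'
#' @param shift Axial shift at the image plane (any length unit).
#' @param M Lateral magnification (> 0).
#' @return Axial shift in sample space, same unit as `shift`.
#' @export
axial_image_to_sample <- function(shift, M) {
  if (!is.numeric(M) || any(M <= 0)) {
    stop("invalid magnification: M must be > 0", call. = FALSE)
  }
  shift / M^2
}

#' Axial misalignment equivalence between the two objectives
#'
#' The primary and remote objectives are conjugated through their tube lenses,
#' so a unit axial displacement of the primary objective is equivalent to a
#' (f_tl2 / f_tl1)^2 displacement of the remote objective (longitudinal
#' magnification of the relay). For the 180/321 mm pair the factor is 3.18:
#' a +/- 1 mm excursion of the primary objective during focusing corresponds
#' to roughly +/- 3 mm of remote-objective travel.
#'
#' @param cfg An [optical_config()].
#' @return Dimensionless equivalence factor (f_tl2 / f_tl1)^2.
#' @export
misalignment_equivalence_factor <- function(cfg) {
  cfg <- as_optical_config(cfg)
  (cfg$f_tl2 / cfg$f_tl1)^2
}

#' One-dimensional beam expansion of a cylindrical-lens telescope
#'
#' @param f_first Focal length of the first cylindrical lens (mm).
#' @param f_last Focal length of the last cylindrical lens (mm).
#' @return Expansion factor `f_last / f_first` (4 for the 25/100 mm pair).
#' @export
cylindrical_expansion <- function(f_first, f_last) {
  if (!is.numeric(f_first) || !is.numeric(f_last) ||
      any(f_first <= 0) || any(f_last <= 0)) {
    stop("invalid focal lengths: must be > 0", call. = FALSE)
  }
  f_last / f_first
}

#' Percent change of a measurement relative to a reference
#'
#' Convenience for characterization summaries, e.g. the growth of the mean
#' lateral FWHM of the remote-focusing path relative to the epifluorescence
#' reference: `percent_change(264, 238)` is about +11.
#'
#' @param value New value.
#' @param reference Reference value (nonzero).
#' @return Signed percent change, `100 * (value - reference) / reference`.
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be nonzero", call. = FALSE)
  100 * (value - reference) / reference
}

#' First-order design report for an OPM remote-focusing train
#'
#' Collects the closed-form design quantities for a configuration: ideal
#' remote tube-lens focal length, residual magnification mismatch of the
#' installed lens, sample-space field of view and scan range for a given
#' image-plane aperture, sample-space field-curvature shift, and the
#' misalignment equivalence factor.
#'
#' @param cfg An [optical_config()].
#' @param image_diameter_mm Usable image-plane diameter at the galvo pair (mm).
#' @param scan_range_mm Half scan range at the image plane (mm).
#' @param field_curvature_mm Image-plane axial focal shift across the scan (mm).
#' @return A named list of design values (lengths in the units noted).
#' @export
design_report <- function(cfg = optical_config(), image_diameter_mm = 20,
                          scan_range_mm = 10, field_curvature_mm = 0.92) {
  cfg <- as_optical_config(cfg)
  f_ideal <- remote_tube_lens_focal(cfg)
  remote_mag <- cfg$M1_nominal * (cfg$f_design / cfg$M2_nominal) / cfg$f_tl2
  list(
    f_tl2_ideal_mm = f_ideal,
    remote_magnification = remote_mag,
    index_ratio = cfg$n1 / cfg$n2,
    magnification_mismatch_pct = percent_change(remote_mag, cfg$n1 / cfg$n2),
    fov_sample_um = 1000 * lateral_image_to_sample(image_diameter_mm,
                                                   cfg$M1_nominal),
    scan_range_sample_um = 1000 * lateral_image_to_sample(scan_range_mm,
                                                          cfg$M1_nominal),
    field_curvature_sample_nm = 1e6 * axial_image_to_sample(field_curvature_mm,
                                                            cfg$M1_nominal),
    misalignment_factor = misalignment_equivalence_factor(cfg)
  )
}
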