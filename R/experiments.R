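# Synthetic emulations of the characterization experiments: a coverslip bead
# field stepped through depths, the remote-objective displacement sweep, and
# the two-level (ratio x objective position) scan calibration sweep. These
# compose the simulator with the estimation pipeline end to end.

#' Shift a bead scene to a sample depth
#'
#' Emulates moving the sample piezo: every bead's depth is offset by `depth`
#' um while lateral positions stay fixed.
#'
#' @param truth A [scene_truth()].
#' @param depth Depth offset (um).
#' @return A [scene_truth()] at the new depth.
#' @export
shift_scene_depth <- function(truth, depth) {
  truth$positions$z <- truth$positions$z + depth
  truth$fov <- NULL  # the declared box no longer applies
  truth
}

#' Render a depth series of a bead scene
#'
#' Renders the reference stack at the focal plane and one stack per requested
#' depth, each centred on the (shifted) bead plane, mirroring the procedure
#' of stepping the sample piezo and re-scanning the tertiary objective.
#'
#' @param truth A [scene_truth()] with beads at the focal plane.
#' @param depths Sample depths (um, excluding the Z = 0 reference).
#' @param geometry A [stack_geometry()]; its `z_centre` is overridden per
#'   depth.
#' @param noise A [noise_model()].
#' @param seed Base seed; depth `i` uses `seed + i`.
#' @return List with `ref` (stack at Z = 0) and `stacks` (named by depth).
#' @export
render_depth_series <- function(truth, depths, geometry,
                                noise = noise_model(), seed = 1) {
  geom_at <- function(zc) {
    g <- geometry; g$z_centre <- zc; g
  }
  ref <- render_stack(truth, geom_at(0), noise, seed = seed)
  stacks <- lapply(seq_along(depths), function(i) {
    render_stack(shift_scene_depth(truth, depths[i]), geom_at(depths[i]),
                 noise, seed = seed + i)
  })
  names(stacks) <- as.character(depths)
  list(ref = ref, stacks = stacks)
}

#' Simulate the remote-objective displacement sweep
#'
#' Emulates the distortion characterization: for each axial displacement D of
#' the remote objective, the injected radial distortion rate is
#' `distortion_gain * (D - D0_true)` (fraction per um of depth), a coverslip
#' bead field is imaged at the focal plane and at each depth, and the percent
#' magnification error rate is estimated per displacement. A final linear fit
#' across displacements locates the zero-distortion optimum.
#'
#' @param displacements Remote-objective displacements D (mm).
#' @param depths Sample depths per displacement (um).
#' @param distortion_gain Distortion rate per mm of displacement
#'   (fraction / (um mm)).
#' @param D0_true True optimal displacement (mm).
#' @param n_beads,fov,min_separation Bead-field parameters (see
#'   [generate_bead_field()]); the field is redrawn per displacement.
#' @param geometry A [stack_geometry()].
#' @param noise A [noise_model()].
#' @param seed Base seed.
#' @param ... Passed to [generate_bead_field()] (flux, psf_model, ...).
#' @return List with `rates` (data frame displacement / error_rate / stderr),
#'   `optimum` (from [optimal_remote_position()]), `profiles`, and the truth
#'   parameters.
#' @export
simulate_distortion_sweep <- function(displacements = seq(-5, 5, by = 1),
                                      depths = c(-10, -5, 5, 10),
                                      distortion_gain = 1e-4, D0_true = 0.4,
                                      n_beads = 120, fov = c(50, 50, 0),
                                      min_separation = 2.5,
                                      geometry = stack_geometry(501, 501, 24),
                                      noise = noise_model(), seed = 1, ...) {
  profiles <- lapply(seq_along(displacements), function(i) {
    D <- displacements[i]
    truth <- generate_bead_field(
      fov = fov, n_beads = n_beads, min_separation = min_separation,
      seed = seed + 1000L * i,
      distortion_rate = distortion_gain * (D - D0_true), ...)
    ser <- render_depth_series(truth, depths, geometry, noise,
                               seed = seed + 1000L * i + 100L)
    magnification_error_profile(ser$ref, ser$stacks, depths = depths,
                                remote_displacement = D)
  })
  rates <- data.frame(
    displacement = displacements,
    error_rate = vapply(profiles, `[[`, numeric(1), "error_rate"),
    stderr = vapply(profiles, `[[`, numeric(1), "error_rate_stderr")
  )
  optimum <- optimal_remote_position(rates$displacement, rates$error_rate)
  list(rates = rates, optimum = optimum, profiles = profiles,
       distortion_gain = distortion_gain, D0_true = D0_true)
}

#' Default agarose-like bead volume for a scan calibration sweep
#'
#' Draws a dense bead field filling the scanned volume implied by the scan
#' geometry (plus a lateral margin of one scan step).
#'
#' @param geometry A [scan_geometry()].
#' @param density Beads per cubic um; 2 by default, a dense agarose phantom.
#' @param seed RNG seed.
#' @param ... Passed to [generate_bead_field()].
#' @return A [scene_truth()].
#' @export
agarose_scene <- function(geometry, density = 2, seed = 1, ...) {
  g <- geometry
  th <- g$tilt_deg * pi / 180
  Lx <- g$n_steps * g$step_x + g$n_obl * g$pixel_obl * cos(th)
  Ly <- g$ny * g$pixel_y
  Lz <- g$n_obl * g$pixel_obl * sin(th)
  n <- max(1L, round(density * Lx * Ly * Lz))
  generate_bead_field(fov = c(Lx, Ly, Lz), n_beads = n, min_separation = 0,
                      seed = seed, ...)
}

#' Simulate the two-level scan voltage-ratio calibration
#'
#' Emulates the mirror calibration: at each primary-objective Z position a
#' fresh agarose bead volume is rendered once (noise-free base), then imaged
#' once per voltage ratio with fresh camera noise -- the same volume is
#' scanned repeatedly, exactly as in the experiment. Each sweep yields the
#' zero-slope ratio; the per-position optima are fitted with a straight line
#' to produce the calibration curve.
#'
#' @param objective_zs Primary objective Z positions (mm).
#' @param ratios Voltage ratios swept at every position.
#' @param geometry A [scan_geometry()].
#' @param density Bead density for [agarose_scene()] (per um^3).
#' @param noise A [noise_model()].
#' @param seed Base seed.
#' @param ... Passed to [agarose_scene()] / [generate_bead_field()]
#'   (ratio_opt_map, gradient_gain, flux, ...).
#' @return List with `curve` (a [calibration_curve()]), `sweeps` (one
#'   `ratio_sweep_result` per position), and `truth_map` (the injected
#'   `c(a, b)`).
#' @export
simulate_calibration_experiment <- function(objective_zs = 0:9,
                                            ratios = seq(1.013, 1.041,
                                                         length.out = 15),
                                            geometry = scan_geometry(
                                              n_steps = 100, step_x = 1.4,
                                              ny = 128, n_obl = 80,
                                              pixel_y = 0.25,
                                              pixel_obl = 0.25),
                                            density = 2,
                                            noise = noise_model(), seed = 1,
                                            ...) {
  truth_map <- NULL
  sweeps <- lapply(seq_along(objective_zs), function(i) {
    z <- objective_zs[i]
    truth <- agarose_scene(geometry, density = density,
                           seed = seed + 10000L * i, ...)
    truth_map <<- truth$ratio_opt_map
    base <- render_oblique_series(truth, geometry)
    series <- lapply(seq_along(ratios), function(j) {
      apply_scan_illumination(base, truth, ratios[j], objective_z = z,
                              noise = noise,
                              seed = seed + 10000L * i + j)
    })
    measure_ratio_sweep(series, ratios, objective_z = z)
  })
  opts <- vapply(sweeps, `[[`, numeric(1), "ratio_opt")
  curve <- calibration_curve(objective_zs, opts)
  list(curve = curve, sweeps = sweeps, truth_map = truth_map)
}
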