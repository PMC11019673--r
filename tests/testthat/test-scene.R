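test_that("bead fields are reproducible and respect the separation contract", {
  t1 <- generate_bead_field(c(50, 50, 10), 200, min_separation = 2, seed = 3)
  t2 <- generate_bead_field(c(50, 50, 10), 200, min_separation = 2, seed = 3)
  expect_identical(t1$positions, t2$positions)
  expect_equal(nrow(t1$positions), 200)
  d <- as.matrix(stats::dist(t1$positions))
  diag(d) <- Inf
  expect_gte(min(d), 2)
  # positions stay inside the declared box
  expect_true(all(abs(t1$positions$x) <= 25 & abs(t1$positions$z) <= 5))
  # single bead: no separation check applies
  expect_equal(nrow(generate_bead_field(c(10, 10, 0), 1, 5, seed = 1)$positions),
               1)
  # infeasible density errors out
  expect_error(generate_bead_field(c(1, 1, 0), 5, min_separation = 10,
                                   seed = 1),
               "density infeasible")
})

test_that("rendering is deterministic and conserves integrated bead flux", {
  sc <- small_clean_scene()
  geom <- stack_geometry(301, 301, 54)
  s1 <- render_stack(sc$truth, geom, noise_model(TRUE, 1.6), seed = 99)
  s2 <- render_stack(sc$truth, geom, noise_model(TRUE, 1.6), seed = 99)
  expect_identical(s1$voxels, s2$voxels)
  # noise-free counts integrate to n_beads * flux (beads are >= 3 sigma from
  # the borders in this scene)
  total <- sum(sc$stack$voxels)
  expect_lt(abs(total / (25 * sc$truth$flux) - 1), 1e-3)
})

test_that("a noise-free centred bead is rendered at the injected FWHMs", {
  truth <- scene_truth(data.frame(x = 0, y = 0, z = 0))
  stk <- render_stack(truth, stack_geometry(61, 61, 54), noise_model(FALSE, 0))
  rec <- measure_psfs(stk)
  expect_equal(nrow(rec), 1)
  expect_true(rec$fit_ok)
  expect_lt(abs(rec$r), 1e-6)
  expect_lt(abs(rec$fwhm_lat / truth$psf_model$fwhm_lat0 - 1), 0.01)
  expect_lt(abs(rec$fwhm_z / truth$psf_model$fwhm_ax0 - 1), 0.01)
})

test_that("radial distortion displaces beads by r x rate x depth", {
  # bead at r = 10 um, depth +10 um, rate 5e-4/um -> 0.05 um outward shift
  truth <- scene_truth(data.frame(x = 10, y = 0, z = 10),
                       distortion_rate = 5e-4)
  stk <- render_stack(truth, stack_geometry(221, 221, 30, z_centre = 10),
                      noise_model(FALSE, 0))
  rec <- measure_psfs(stk)
  expect_equal(rec$x, 10 * (1 + 5e-4 * 10), tolerance = 1e-5)
  # zero distortion: position identical at depth
  truth0 <- scene_truth(data.frame(x = 10, y = 0, z = 10))
  rec0 <- measure_psfs(render_stack(truth0,
                                    stack_geometry(221, 221, 30,
                                                   z_centre = 10),
                                    noise_model(FALSE, 0)))
  expect_equal(rec0$x, 10, tolerance = 1e-5)
})

test_that("the PSF field grows linearly in radius and depth", {
  m <- psf_field_model(fwhm_lat0 = 200, fwhm_ax0 = 600, radial_growth = 1e-3,
                       depth_growth_lat = 0.01, depth_growth_ax = 0.02)
  expect_equal(psf_fwhm_at(m, 0, 0)$fwhm_lat, 200)
  expect_equal(psf_fwhm_at(m, 50, 0)$fwhm_lat, 200 * 1.05)
  expect_equal(psf_fwhm_at(m, 0, -10)$fwhm_ax, 600 * 1.2)
  expect_error(psf_field_model(fwhm_lat0 = 300, fwhm_ax0 = 200), "fwhm_ax0")
  expect_error(psf_field_model(radial_growth = -1), "growth")
})

test_that("scan series carry the injected illumination gradient exactly", {
  g <- scan_geometry(n_steps = 40, step_x = 1.4, ny = 40, n_obl = 40,
                     pixel_y = 0.25, pixel_obl = 0.25)
  truth <- agarose_scene(g, density = 0.1, seed = 5)
  base <- render_oblique_series(truth, g)
  rho0 <- truth_ratio_opt(truth, 0)
  # matched ratio, no noise: the base series is returned unchanged
  ser0 <- apply_scan_illumination(base, truth, rho0, 0, noise_model(FALSE, 0))
  expect_equal(ser0$voxels, base$voxels)
  # mismatch: frame s is scaled by 1 + G * drho * (s - (n-1)/2) exactly
  drho <- 0.01
  ser <- apply_scan_illumination(base, truth, rho0 + drho, 0,
                                 noise_model(FALSE, 0))
  s <- 11
  fac <- 1 + truth$gradient_gain * drho * (s - 1 - (g$n_steps - 1) / 2)
  expect_equal(ser$voxels[, , s], base$voxels[, , s] * fac)
  # scan extent bookkeeping: 100 steps x 1.4 um covers 140 um
  expect_equal(scan_geometry(100, 1.4)$n_steps * scan_geometry(100, 1.4)$step_x,
               140)
  expect_error(scan_geometry(n_steps = 2), "too short")
})

test_that("oblique rendering places flux consistently with the shear map", {
  # sampling fine enough (~1 sigma per voxel) that the point-sampled
  # Gaussian sums to its integral
  g <- scan_geometry(n_steps = 120, step_x = 0.117, ny = 120, n_obl = 120,
                     pixel_y = 0.117, pixel_obl = 0.117)
  truth <- scene_truth(data.frame(x = 0, y = 1, z = 0.5))
  base <- render_oblique_series(truth, g)
  # total flux conserved (bead well inside the scanned volume)
  expect_lt(abs(sum(base$voxels) / truth$flux - 1), 1e-3)
  # flux-weighted centroid sits at the sheared index position
  th <- 28 * pi / 180
  w <- base$voxels / sum(base$voxels)
  co <- sum(slice.index(w, 2) * w) - 1
  cs <- sum(slice.index(w, 3) * w) - 1
  cy <- sum(slice.index(w, 1) * w) - 1
  expect_equal(co, 0.5 / (0.117 * sin(th)) + (g$n_obl - 1) / 2,
               tolerance = 1e-3)
  expect_equal(cy, 1 / 0.117 + (g$ny - 1) / 2, tolerance = 1e-3)
  expect_equal(cs, (0 - 0.5 / tan(th)) / 0.117 + (g$n_steps - 1) / 2,
               tolerance = 1e-2)
})

test_that("stacks survive a TIFF + sidecar round trip", {
  truth <- generate_bead_field(c(10, 10, 0), 5, 1.5, seed = 2)
  stk <- render_stack(truth, stack_geometry(101, 101, 8),
                      noise_model(TRUE, 1.6), seed = 3)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".yaml"))))
  write_stack_tiff(stk, path, truth = truth)
  back <- read_stack_tiff(path)
  expect_equal(back$modality, "straight")
  expect_equal(back$pixel_xy, stk$pixel_xy)
  # counts restored up to 16-bit quantization of the full scale
  expect_lt(max(abs(back$voxels - stk$voxels)), max(stk$voxels) / 2^15)
  tr <- read_truth_sidecar(path)
  expect_equal(tr$positions$x, truth$positions$x)
  expect_equal(tr$psf_model$fwhm_lat0, truth$psf_model$fwhm_lat0)
  expect_equal(tr$ratio_opt_map, truth$ratio_opt_map)
})
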