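test_that("variance-of-Laplacian focus metric behaves as a sharpness score", {
  expect_equal(focus_metric(matrix(5, 20, 20)), 0)
  img <- matrix(0, 31, 31); img[16, 16] <- 100
  blur <- atrous_planes(img, 1)$A
  expect_gt(focus_metric(img), focus_metric(blur))
  # invariant to constant offsets
  expect_equal(focus_metric(img + 37.5), focus_metric(img))
})

test_that("best focus frame recovers the simulated focal plane", {
  # a single bead at depth z sits at frame z/step + centre; symmetric scene
  truth <- scene_truth(data.frame(x = 0, y = 0, z = 0))
  stk <- render_stack(truth, stack_geometry(61, 61, 21, step_z = 0.3),
                      noise_model(FALSE, 0))
  expect_equal(best_focus_frame(stk), 11)
  # off-centre truth plane is recovered too
  truth2 <- scene_truth(data.frame(x = 0, y = 0, z = 0.9))
  stk2 <- render_stack(truth2, stack_geometry(61, 61, 21, step_z = 0.3),
                       noise_model(FALSE, 0))
  expect_equal(best_focus_frame(stk2), 14)
  # monotonically blurred sequence: first frame wins
  img <- matrix(0, 41, 41); img[21, 21] <- 50
  seq3 <- array(0, c(41, 41, 4))
  seq3[, , 1] <- img
  for (k in 2:4) seq3[, , k] <- atrous_planes(seq3[, , k - 1], 1)$A
  expect_equal(best_focus_frame(seq3), 1)
})

test_that("wavelet detection finds essentially all beads and nothing else", {
  sc <- default_noisy_scene()
  rec <- default_noisy_records()
  idx <- match_records_to_truth(rec, sc$truth)
  ok <- rec$fit_ok
  # >= 95% of the 500 true beads recovered
  expect_gte(length(unique(stats::na.omit(idx))), 0.95 * 500)
  # no spurious detections among usable records
  expect_true(all(!is.na(idx[ok])))
})

test_that("blank noise images yield no candidates at the default threshold", {
  set.seed(2024)
  counts <- vapply(1:25, function(i) {
    nrow(detect_beads(matrix(pmax(0, stats::rnorm(256^2, 0, 1.6)), 256)))
  }, numeric(1))
  expect_true(mean(counts == 0) >= 0.95)
})

test_that("candidates closer than the minimum separation merge", {
  truth <- scene_truth(data.frame(x = c(-0.15, 0.15), y = c(0, 0),
                                  z = c(0, 0)))
  stk <- render_stack(truth, stack_geometry(61, 61, 5), noise_model(FALSE, 0))
  cand <- detect_beads(stk$voxels[, , 3])
  expect_equal(nrow(cand), 1)
})

test_that("2D Gaussian fits are exact on analytic renders", {
  for (sig in c(0.9, 1.2, 2.2, 3.4)) {  # FWHM ~2.1 to 8 px
    x <- 0:30; y <- 0:30
    img <- 10 + 200 * exp(-outer((y - 15.3)^2, (x - 14.6)^2, "+") /
                            (2 * sig^2))
    f <- fit_bead_2d(img, c(15, 15), roi_halfwidth = 5)
    expect_true(f$fit_ok)
    expect_lt(abs(f$fwhm_x / (FWHM_SIGMA * sig) - 1), 0.005)
    expect_lt(abs(f$fwhm_y / (FWHM_SIGMA * sig) - 1), 0.005)
    expect_equal(f$x, 14.6, tolerance = 1e-4)
    expect_equal(f$y, 15.3, tolerance = 1e-4)
    expect_equal(f$background, 10, tolerance = 1e-3)
  }
  # ROI clipped by the border: flagged, not fitted
  img <- matrix(1, 21, 21)
  expect_false(fit_bead_2d(img, c(2, 10), roi_halfwidth = 5)$fit_ok)
})

test_that("axial profiles recover the injected axial FWHM", {
  truth <- scene_truth(data.frame(x = 0.2, y = -0.3, z = 0),
                       psf_model = psf_field_model(fwhm_ax0 = 688))
  stk <- render_stack(truth, stack_geometry(61, 61, 54), noise_model(FALSE, 0))
  f2 <- fit_bead_2d(stk$voxels[, , best_focus_frame(stk)],
                    c(0.2 / 0.1083 + 30, -0.3 / 0.1083 + 30))
  ax <- fit_axial_profile(stk, f2$x, f2$y)
  expect_true(ax$fit_ok)
  expect_lt(abs(ax$fwhm_z / 688 - 1), 0.01)
  expect_equal(ax$z_best, 0, tolerance = 1e-3)
  # 688 nm FWHM sampled at 150 nm: comfortably >= 4 points above half max
  prof <- stk$voxels[31, 31, ]
  expect_gte(sum(prof > max(prof) / 2), 4)
  # peak at the stack boundary is flagged
  truthe <- scene_truth(data.frame(x = 0, y = 0, z = -3.9))
  stke <- render_stack(truthe, stack_geometry(61, 61, 54),
                       noise_model(FALSE, 0))
  f2e <- fit_bead_2d(stke$voxels[, , 2], c(30, 30))
  expect_false(fit_axial_profile(stke, f2e$x, f2e$y)$fit_ok)
})

test_that("the full cascade recovers the injected radial FWHM trend", {
  # noise-free field with strong radial growth across a 25 um radius
  model <- psf_field_model(fwhm_lat0 = 255, fwhm_ax0 = 688,
                           radial_growth = 4e-3)
  truth <- generate_bead_field(c(46, 46, 0), 60, min_separation = 3,
                               seed = 17, psf_model = model)
  stk <- render_stack(truth, stack_geometry(471, 471, 40),
                      noise_model(FALSE, 0))
  rec <- measure_psfs(stk)
  ok <- rec[rec$fit_ok, ]
  expect_gte(nrow(ok), 55)
  fit <- stats::lm(fwhm_lat ~ r, data = ok)
  slope_inj <- 255 * 4e-3
  expect_lt(abs(stats::coef(fit)[2] / slope_inj - 1), 0.05)
  expect_lt(abs(stats::coef(fit)[1] / 255 - 1), 0.05)
})

test_that("radial summaries aggregate usable records per bin", {
  rec <- data.frame(x = 1, y = 1, z_best = 0,
                    fwhm_x = 260, fwhm_y = 260, fwhm_lat = 260, fwhm_z = 700,
                    amplitude = 100, background = 0,
                    r = c(2, 3, 4, 12, 13, 14, 28), theta = 0,
                    fit_ok = TRUE)
  sm <- summarize_by_radius(rec, c(0, 10, 20, 30), depth_label = 0)
  # identical records: zero SD in occupied bins; sparse last bin dropped
  expect_equal(sm$fwhm_lat_sd, c(0, 0))
  expect_equal(sm$n, c(3L, 3L))
  expect_equal(sm$fwhm_z_mean, c(700, 700))
  # radial monotonicity on the default noisy scene (within 1 SD)
  recs <- default_noisy_records()
  sm2 <- summarize_by_radius(recs, c(0, 12, 24, 36), depth_label = 0)
  expect_gte(nrow(sm2), 3)
  d <- diff(sm2$fwhm_lat_mean)
  expect_true(all(d > -sm2$fwhm_lat_sd[-1]))
  # empty input: empty summary
  expect_equal(nrow(summarize_by_radius(rec[0, ], c(0, 10))), 0)
})
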