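test_that("summed intensity series normalize to unit mean", {
  arr <- array(1, c(8, 8, 10))
  v <- summed_intensity_series(arr)
  expect_equal(v, rep(1, 10))
  # mean is exactly 1 for arbitrary series
  arr2 <- array(stats::runif(8 * 8 * 12), c(8, 8, 12))
  expect_equal(mean(summed_intensity_series(arr2)), 1)
  # injected linear gradient: output = 1 + g (s - mid) exactly
  g <- 0.004
  n <- 50
  fac <- 1 + g * (0:(n - 1) - (n - 1) / 2)
  arr3 <- array(rep(fac, each = 16), c(4, 4, n))
  expect_equal(summed_intensity_series(arr3), fac)
  # short series and all-zero frames
  expect_error(summed_intensity_series(array(1, c(4, 4, 2))), "too short")
  arr4 <- array(1, c(4, 4, 5)); arr4[, , 3] <- 0
  expect_warning(summed_intensity_series(arr4), "all-zero")
})

test_that("slopes are OLS against the step index", {
  expect_equal(slope_for_ratio(rep(1, 20))$slope, 0)
  s <- 3e-4
  vals <- 1 + s * (0:99 - 49.5)
  fit <- slope_for_ratio(vals)
  expect_equal(fit$slope, s, tolerance = 1e-12)
  expect_lt(fit$stderr, 1e-15)
  expect_error(slope_for_ratio(c(1, 2)), ">= 3")
})

test_that("the zero-slope ratio is located and its shift is equivariant", {
  rho <- seq(1.013, 1.041, length.out = 15)
  G <- 0.5
  slopes <- G * (rho - 1.025)
  res <- optimal_ratio(rho, slopes)
  expect_equal(res$ratio_opt, 1.025, tolerance = 1e-12)
  expect_equal(res$gain, G, tolerance = 1e-12)
  expect_false(res$extrapolated)
  # small noise: recovery within 1e-4
  set.seed(8)
  noisy <- slopes + stats::rnorm(15, sd = 2e-6)
  expect_lt(abs(optimal_ratio(rho, noisy)$ratio_opt - 1.025), 1e-4)
  # equivariance: shifting every ratio by delta shifts the optimum by delta
  delta <- 0.004
  res2 <- optimal_ratio(rho + delta, slopes)
  expect_equal(res2$ratio_opt, res$ratio_opt + delta, tolerance = 1e-10)
  # crossing outside the sweep: extrapolated with a warning
  expect_warning(res3 <- optimal_ratio(rho, G * (rho - 1.05)), "extrapolates")
  expect_true(res3$extrapolated)
  expect_equal(res3$ratio_opt, 1.05, tolerance = 1e-10)
  # degenerate sweeps
  expect_error(optimal_ratio(c(1.02, 1.02), c(0, 1)), "distinct")
  expect_error(optimal_ratio(rho, rep(1e-3, 15)), "flat")
})

test_that("simulated sweeps recover slope and optimum through the pipeline", {
  g <- scan_geometry(n_steps = 60, step_x = 1.4, ny = 48, n_obl = 48,
                     pixel_y = 0.25, pixel_obl = 0.25)
  truth <- agarose_scene(g, density = 0.15, seed = 31)
  base <- render_oblique_series(truth, g)
  rho0 <- truth_ratio_opt(truth, 0)
  # noise-free: measured slope equals G * mismatch up to the (deterministic)
  # bead-content contribution, which the same-volume design cancels in the
  # sweep: the fitted optimum shifts by exactly content/G for every ratio,
  # so recover the *difference* of slopes instead
  drho <- c(-0.01, 0.01)
  sl <- vapply(drho, function(d) {
    ser <- apply_scan_illumination(base, truth, rho0 + d, 0,
                                   noise_model(FALSE, 0))
    slope_for_ratio(summed_intensity_series(ser))$slope
  }, numeric(1))
  expect_equal(diff(sl) / diff(drho), truth$gradient_gain, tolerance = 0.05)
  # full sweep through measure_ratio_sweep; because the same volume is imaged
  # at every ratio, the bead-content slope c shifts the crossing by exactly
  # c / G, so compare against that prediction
  content <- slope_for_ratio(summed_intensity_series(
    apply_scan_illumination(base, truth, rho0, 0, noise_model(FALSE, 0))))
  ratios <- rho0 + seq(-0.012, 0.012, length.out = 9)
  series <- lapply(ratios, function(rr) {
    apply_scan_illumination(base, truth, rr, 0, noise_model(TRUE, 1.6),
                            seed = round(rr * 1e5))
  })
  sweep <- measure_ratio_sweep(series, ratios, objective_z = 0)
  expect_equal(nrow(sweep$entries), 9)
  expect_lt(abs(sweep$ratio_opt - (rho0 - content$slope / truth$gradient_gain)),
            1e-3)
})

test_that("calibration curves fit and predict the per-position optima", {
  z <- c(0, 4)
  ro <- c(1.014, 1.025)
  cc <- calibration_curve(z, ro)
  expect_equal(cc$a, 1.014, tolerance = 1e-12)
  expect_equal(cc$b, (1.025 - 1.014) / 4, tolerance = 1e-12)
  expect_equal(predict(cc, z), ro, tolerance = 1e-12)
  # prediction at a sampled position reproduces it within the residual
  z10 <- 0:9
  set.seed(9)
  ro10 <- 1.014 + 0.0028 * z10 + stats::rnorm(10, sd = 1e-4)
  cc10 <- calibration_curve(z10, ro10)
  expect_true(all(abs(predict(cc10, z10) - ro10) <=
                    max(abs(cc10$residuals)) + 1e-12))
  expect_error(calibration_curve(c(1, 1), c(1.0, 1.1)), "distinct")
})
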