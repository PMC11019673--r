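fake_records <- function(r, theta, fit_ok = TRUE) {
  data.frame(x = r * cos(theta), y = r * sin(theta), z_best = 0,
             fwhm_x = 260, fwhm_y = 260, fwhm_lat = 260, fwhm_z = 700,
             amplitude = 100, background = 0, r = r, theta = theta,
             fit_ok = fit_ok)
}

circ_diff_test <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

test_that("polar matching pairs beads by angle and radial proximity", {
  set.seed(4)
  r <- stats::runif(40, 2, 30)
  th <- stats::runif(40, -pi, pi)
  ref <- fake_records(r, th)
  # identical sets: every bead matches itself with zero displacement
  m <- match_beads_polar(ref, ref)
  expect_equal(nrow(m), 40)
  expect_equal(m$dr, rep(0, 40))
  # radially scaled probe: dr = 0.005 * r for every pair
  probe <- fake_records(r * 1.005, th)
  m2 <- match_beads_polar(ref, probe)
  expect_equal(nrow(m2), 40)
  expect_equal(m2$dr, 0.005 * m2$r_ref)
  # a probe-only bead at an unused angle is dropped
  th_orphan <- 2.9999
  extra <- rbind(probe, fake_records(15, th_orphan))
  sub <- ref[abs(circ_diff_test(ref$theta, th_orphan)) > 0.1, ]
  m3 <- match_beads_polar(sub, extra)
  expect_equal(nrow(m3), nrow(sub))
  # empty inputs give an empty pairing
  expect_equal(nrow(match_beads_polar(ref[0, ], probe)), 0)
})

test_that("the radial displacement rate is the scaling factor minus one", {
  r <- c(5, 10, 15, 20, 25)
  pairs <- data.frame(r_ref = r, r_probe = r * 1.01, dr = r * 0.01,
                      dtheta = 0)
  fit <- radial_displacement_rate(pairs)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$stderr, 0, tolerance = 1e-12)
  # degenerate inputs
  expect_error(radial_displacement_rate(pairs[1, ]), ">= 2")
  same_r <- data.frame(r_ref = c(10, 10), r_probe = c(10.1, 10.1),
                       dr = 0.1, dtheta = 0)
  expect_error(radial_displacement_rate(same_r), "rank-deficient")
})

test_that("noise-free per-depth slope matches the injected distortion exactly", {
  truth <- generate_bead_field(c(50, 50, 0), 120, min_separation = 2.5,
                               seed = 5, distortion_rate = 4e-4)
  geom <- stack_geometry(501, 501, 24)
  ser <- render_depth_series(truth, depths = 10, geom, noise_model(FALSE, 0))
  rr <- measure_psfs(ser$ref)
  rd <- measure_psfs(ser$stacks[["10"]])
  rate <- radial_displacement_rate(match_beads_polar(rr, rd))
  expect_lt(abs(rate$slope - 4e-4 * 10), 1e-6)
  # zero injected distortion: slope indistinguishable from zero
  truth0 <- generate_bead_field(c(50, 50, 0), 120, min_separation = 2.5,
                                seed = 5, distortion_rate = 0)
  ser0 <- render_depth_series(truth0, depths = 10, geom,
                              noise_model(FALSE, 0))
  rate0 <- radial_displacement_rate(
    match_beads_polar(measure_psfs(ser0$ref),
                      measure_psfs(ser0$stacks[["10"]])))
  expect_lt(abs(rate0$slope), 1e-6)
})

test_that("the error-rate sign flips with the displacement sign", {
  # constructed profiles: error% = rate * depth with rate = k (D - D0)
  depths <- c(-10, -5, 5, 10)
  mk <- function(rate) rate * depths
  for (D in c(-2, 2)) {
    rate <- 0.01 * (D - 0)
    fit <- stats::lm(mk(rate) ~ 0 + depths)
    expect_equal(unname(stats::coef(fit)[1]), rate)
  }
})

test_that("the optimal remote position is the zero crossing of the rate line", {
  D <- seq(-5, 5, by = 1)
  rates <- 0.011 * (D - 0.4)   # exactly antisymmetric about 0.4
  opt <- optimal_remote_position(D, rates)
  expect_equal(opt$D0, 0.4, tolerance = 1e-10)
  expect_false(opt$extrapolated)
  # single-signed rates with nonzero slope: extrapolated crossing + warning
  expect_warning(opt2 <- optimal_remote_position(1:5, 0.01 * (1:5) + 0.1),
                 "extrapolates")
  expect_true(opt2$extrapolated)
  expect_equal(opt2$D0, -10)
  # flat line has no crossing
  expect_error(optimal_remote_position(1:5, rep(0.02, 5)), "zero crossing")
  expect_error(optimal_remote_position(c(1, 1), c(0, 1)), "distinct")
})
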