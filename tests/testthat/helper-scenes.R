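# Shared synthetic scenes, built once per test run and memoized. Sizes are
# chosen so the whole suite stays comfortably within a few minutes on one
# core while keeping the bead statistics meaningful.

.scene_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, builder(), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

# Default noisy coverslip scene: ~500 beads over a 70 um field, rendered at
# the standard straight-path sampling (0.1083 um pixels, 54 x 150 nm planes).
default_noisy_scene <- function() {
  memo("noisy500", function() {
    truth <- generate_bead_field(fov = c(70, 70, 0), n_beads = 500,
                                 min_separation = 2, seed = 11)
    stack <- render_stack(truth, stack_geometry(739, 739, 54),
                          noise_model(TRUE, 1.6), seed = 12)
    list(truth = truth, stack = stack)
  })
}

default_noisy_records <- function() {
  memo("noisy500_records", function() {
    measure_psfs(default_noisy_scene()$stack)
  })
}

# Small noise-free scene for exactness checks.
small_clean_scene <- function() {
  memo("clean25", function() {
    truth <- generate_bead_field(fov = c(30, 30, 0), n_beads = 25,
                                 min_separation = 2.5, seed = 7)
    stack <- render_stack(truth, stack_geometry(301, 301, 54),
                          noise_model(FALSE, 0))
    list(truth = truth, stack = stack)
  })
}

# Match usable records to true beads within `tol` um; returns indices into
# truth$positions for each record row (NA when unmatched).
match_records_to_truth <- function(records, truth, tol = 0.11) {
  ok <- records$fit_ok
  idx <- rep(NA_integer_, nrow(records))
  if (!any(ok)) return(idx)
  d2 <- outer(records$x[ok], truth$positions$x, "-")^2 +
    outer(records$y[ok], truth$positions$y, "-")^2
  best <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_along(best), best)])
  best[dist > tol] <- NA_integer_
  idx[ok] <- best
  idx
}

# Injected FWHMs at the true (r, depth) of given truth rows.
injected_fwhm <- function(truth, rows, depth = NULL) {
  p <- truth$positions[rows, , drop = FALSE]
  z <- if (is.null(depth)) p$z else depth
  psf_fwhm_at(truth$psf_model, sqrt(p$x^2 + p$y^2), z)
}
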