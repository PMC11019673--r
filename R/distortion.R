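# Depth-dependent magnification distortion of the remote focusing volume:
# polar bead matching against the focal-plane reference, per-depth radial
# displacement rates, and the optimal remote-objective position.

#' Match beads between depths in polar coordinates
#'
#' For each bead of the probe set, candidate reference beads are those with
#' the same polar angle within `theta_tol` (circular difference); the match is
#' the candidate with the smallest radial separation. One-to-one matching is
#' enforced greedily by ascending |delta r|; unmatched beads are dropped.
#' Both record sets must share the image-centre origin.
#'
#' @param ref Bead records at the focal plane (Z = 0), from [measure_psfs()].
#' @param probe Bead records at depth Z.
#' @param theta_tol Polar-angle tolerance in radians (default 2 degrees).
#' @param usable_only Match only records with `fit_ok`.
#' @return Data frame of pairs: `r_ref`, `r_probe`, `dr`, `dtheta`.
#' @export
match_beads_polar <- function(ref, probe, theta_tol = 2 * pi / 180,
                              usable_only = TRUE) {
  if (usable_only) {
    ref <- ref[ref$fit_ok, , drop = FALSE]
    probe <- probe[probe$fit_ok, , drop = FALSE]
  }
  empty <- data.frame(r_ref = numeric(0), r_probe = numeric(0),
                      dr = numeric(0), dtheta = numeric(0))
  if (nrow(ref) == 0 || nrow(probe) == 0) return(empty)
  cand <- do.call(rbind, lapply(seq_len(nrow(probe)), function(i) {
    dth <- circ_diff(probe$theta[i], ref$theta)
    j <- which(abs(dth) <= theta_tol)
    if (!length(j)) return(NULL)
    data.frame(probe = i, ref = j,
               dr = probe$r[i] - ref$r[j], dtheta = dth[j])
  }))
  if (is.null(cand)) return(empty)
  cand <- cand[order(abs(cand$dr)), , drop = FALSE]
  used_p <- logical(nrow(probe)); used_r <- logical(nrow(ref))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_p[cand$probe[k]] && !used_r[cand$ref[k]]) {
      keep[k] <- TRUE
      used_p[cand$probe[k]] <- TRUE
      used_r[cand$ref[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(r_ref = ref$r[cand$ref], r_probe = probe$r[cand$probe],
                    dr = cand$dr, dtheta = cand$dtheta)
  rownames(out) <- NULL
  out
}

circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Radial displacement rate at one depth
#'
#' Least-squares fit of the radial displacement `dr` against the reference
#' radius, with the intercept fixed at zero (under the radial-scaling model a
#' bead at the centre cannot displace). The slope is the fractional
#' magnification error at that depth; multiply by 100 for percent.
#'
#' @param pairs Matched pairs from [match_beads_polar()] (>= 2, spanning
#'   distinct radii).
#' @return List with `slope`, `stderr`, `n`.
#' @export
radial_displacement_rate <- function(pairs) {
  if (nrow(pairs) < 2) stop("need >= 2 matched pairs", call. = FALSE)
  if (max(pairs$r_ref) - min(pairs$r_ref) < 1e-9) {
    stop("rank-deficient fit: all pairs at identical radius", call. = FALSE)
  }
  fit <- ols_origin(pairs$r_ref, pairs$dr)
  list(slope = fit$b, stderr = fit$b_stderr, n = nrow(pairs))
}

#' Magnification error profile across depths for one remote-objective position
#'
#' Runs [measure_psfs()] on the reference stack (Z = 0) and on each depth
#' stack, matches each depth against the reference in polar coordinates,
#' computes the per-depth percent magnification error, and fits the error
#' against depth with a line through the origin (Z = 0 is the self-reference).
#' The slope of that line is the error rate in percent per um of depth, the
#' Fig.-4-style summary of one remote-objective position; the adopted sign
#' convention is positive = apparent magnification increase above the focal
#' plane.
#'
#' @param ref_stack Straight-modality [bead_stack()] at Z = 0.
#' @param depth_stacks Named-by-depth list of stacks (or list of
#'   `list(depth =, stack =)`); depths in um.
#' @param depths Numeric depths (um) if `depth_stacks` is unnamed.
#' @param remote_displacement Remote-objective displacement D (mm), copied to
#'   the output.
#' @param theta_tol Passed to [match_beads_polar()].
#' @param ... Passed to [measure_psfs()].
#' @return List with `error_rate` (%/um), `error_rate_stderr`, `per_depth`
#'   (data frame depth/error_pct/stderr_pct/n_pairs), and `displacement`.
#' @export
magnification_error_profile <- function(ref_stack, depth_stacks,
                                        depths = NULL,
                                        remote_displacement = NA_real_,
                                        theta_tol = 2 * pi / 180, ...) {
  if (is.null(depths)) depths <- as.numeric(names(depth_stacks))
  stopifnot(length(depths) == length(depth_stacks), !anyNA(depths))
  if (length(depths) < 2) {
    stop("need >= 2 usable depths for an error profile", call. = FALSE)
  }
  ref_rec <- measure_psfs(ref_stack, ...)
  per <- do.call(rbind, lapply(seq_along(depths), function(i) {
    rec <- measure_psfs(depth_stacks[[i]], ...)
    pairs <- match_beads_polar(ref_rec, rec, theta_tol)
    if (nrow(pairs) < 2) {
      return(data.frame(depth = depths[i], error_pct = NA_real_,
                        stderr_pct = NA_real_, n_pairs = nrow(pairs)))
    }
    rate <- radial_displacement_rate(pairs)
    data.frame(depth = depths[i], error_pct = 100 * rate$slope,
               stderr_pct = 100 * rate$stderr, n_pairs = rate$n)
  }))
  usable <- !is.na(per$error_pct)
  if (sum(usable) < 2) {
    stop("fewer than 2 depths produced a usable error estimate", call. = FALSE)
  }
  fit <- ols_origin(per$depth[usable], per$error_pct[usable])
  list(error_rate = fit$b, error_rate_stderr = fit$b_stderr,
       per_depth = per, displacement = remote_displacement)
}

#' Optimal remote-objective position from an error-rate sweep
#'
#' Linear fit of the magnification error rate against the remote-objective
#' displacement; the zero crossing D0 is the position where the magnification
#' stays constant throughout the remote volume. A warning is issued when D0
#' extrapolates beyond the sampled displacement range.
#'
#' @param displacements Remote-objective displacements D (mm, >= 2 distinct).
#' @param rates Error rates (%/um) at those displacements.
#' @return List with `D0` (mm), `D0_stderr` (delta-method), `slope`,
#'   `intercept`, `extrapolated`.
#' @export
optimal_remote_position <- function(displacements, rates) {
  stopifnot(length(displacements) == length(rates))
  if (length(unique(displacements)) < 2) {
    stop("need >= 2 distinct displacements", call. = FALSE)
  }
  fit <- ols_line(displacements, rates)
  if (abs(fit$b) < .Machine$double.eps^0.5 * max(abs(rates), 1)) {
    stop("no zero crossing: fitted slope is zero", call. = FALSE)
  }
  d0 <- -fit$a / fit$b
  grad <- c(-1 / fit$b, fit$a / fit$b^2)
  d0_se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  extrap <- d0 < min(displacements) || d0 > max(displacements)
  if (extrap) {
    warning("optimal position extrapolates beyond the sampled displacements")
  }
  list(D0 = d0, D0_stderr = d0_se, slope = fit$b, intercept = fit$a,
       extrapolated = extrap)
}
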