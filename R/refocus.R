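#' Fresnel phase-only defocus filter
#'
#' Builds the quadratic-phase spatial-frequency filter
#' `exp(sign * i * pi * lambda_c * zd * (fx^2 + fy^2))` on the unshifted DFT
#' frequency grid implied by the lateral pitches. With `sign = -1` this is the
#' refocusing (deconvolution) filter for a plane defocused by `zd`; with
#' `sign = +1` its exact complex conjugate, i.e. the forward defocusing
#' filter. The filter is phase-only: unit modulus at every frequency.
#'
#' @param shape Integer vector `c(n_y, n_x)`: the (padded) en face shape the
#'   filter is applied to.
#' @param geometry A [scan_geometry()] supplying the lateral pitches and
#'   center wavelength.
#' @param zd Signed defocus distance in um. Positive `zd` means the en face
#'   plane lies deeper than the focal plane.
#' @param sign `-1` (refocus) or `+1` (defocus).
#' @return Complex matrix `(n_y, n_x)`.
#' @export
fresnel_filter <- function(shape, geometry, zd, sign = -1) {
  if (!sign %in% c(-1, 1)) stop("sign must be -1 (refocus) or +1 (defocus)")
  if (!is.finite(zd)) stop("zd must be finite")
  fy <- dft_freqs(shape[1], geometry$lateral_pitch_y)
  fx <- dft_freqs(shape[2], geometry$lateral_pitch_x)
  phase <- pi * geometry$center_wavelength * zd * outer(fy^2, fx^2, "+")
  exp((0 + 1i) * sign * phase)
}

#' Propagate (refocus or defocus) an en face complex field
#'
#' Applies the Fresnel phase filter in the spatial-frequency domain:
#' zero-pad by `pad_width` pixels on all four sides, 2-D FFT, multiply by
#' [fresnel_filter()], inverse FFT, and truncate the padding. The zero padding
#' absorbs the blurred field edge so that it cannot alias into the opposite
#' side of the field; the returned field has the input shape.
#'
#' @param field Complex matrix `(n_y, n_x)`.
#' @param geometry A [scan_geometry()].
#' @param zd Signed defocus distance in um.
#' @param sign `-1` (refocus) or `+1` (defocus).
#' @param pad_width Zero-padding width in pixels (default 50).
#' @param amplitude_filter Optional real matrix of the padded shape multiplied
#'   onto the spectrum together with the phase filter (used by the simulator's
#'   confocal beam-envelope option; `NULL` for pure phase-only propagation).
#' @return Complex matrix of the same shape as `field`.
#' @export
propagate_enface <- function(field, geometry, zd, sign = -1, pad_width = 50L,
                             amplitude_filter = NULL) {
  pad_width <- as.integer(pad_width)
  if (pad_width < 0L) stop("pad_width must be >= 0")
  if (!is.matrix(field)) stop("field must be a 2-D matrix")
  if (zd == 0 && is.null(amplitude_filter)) return(field + 0i)
  ny <- nrow(field); nx <- ncol(field)
  py <- ny + 2L * pad_width; px <- nx + 2L * pad_width
  padded <- matrix(0 + 0i, py, px)
  padded[pad_width + seq_len(ny), pad_width + seq_len(nx)] <- field
  H <- fresnel_filter(c(py, px), geometry, zd, sign)
  if (!is.null(amplitude_filter)) H <- H * amplitude_filter
  out <- stats::fft(stats::fft(padded) * H, inverse = TRUE) / (py * px)
  out[pad_width + seq_len(ny), pad_width + seq_len(nx)]
}

#' Information entropy of a linear-intensity image
#'
#' `E = -sum(p_i log p_i)` with `p_i = I_i / sum(I)` and `0 log 0 := 0`
#' (natural logarithm). Sharp images concentrate intensity in few pixels and
#' have low entropy; defocus spreads intensity and raises it, which is what
#' the defocus estimator exploits.
#'
#' @param intensity Nonnegative numeric vector/matrix, not all zero.
#' @return Scalar entropy (nats).
#' @export
image_entropy <- function(intensity) {
  intensity <- as.numeric(intensity)
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  s <- sum(intensity)
  if (s <= 0) stop("intensity must not be all zero")
  p <- intensity / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Estimate the defocus of a single en face plane
#'
#' Finds the defocus `zd` whose refocusing filter minimizes the information
#' entropy of the refocused linear-intensity image, by quasi-Newton (BFGS)
#' search followed by a golden-section polish to the 1 nm step tolerance.
#' If the BFGS run barely moves from its start (a symptom of the flat
#' entropy landscape inside the depth of focus), restarts from `+/-
#' restart_offset` are tried and the best entropy wins.
#'
#' @param field Complex en face matrix with speckle content.
#' @param geometry A [scan_geometry()].
#' @param zd_init Starting defocus (um).
#' @param pad_width Zero padding used for each trial refocus.
#' @param restart_offset Restart magnitude in um; defaults to the geometry's
#'   DOF half-width.
#' @param tol_um Final tolerance on zd in um (default 1e-3 um = 1 nm).
#' @param maxit BFGS iteration cap.
#' @return List with `zd` (um), `entropy` at the optimum, and `converged`.
#' @export
estimate_defocus_plane <- function(field, geometry, zd_init = 0,
                                   pad_width = 50L, restart_offset = NULL,
                                   tol_um = 1e-3, maxit = 200L) {
  if (is.null(restart_offset)) restart_offset <- dof_halfwidth(geometry)
  obj <- function(zd)
    image_entropy(Mod(propagate_enface(field, geometry, zd, sign = -1,
                                       pad_width = pad_width))^2)
  run <- function(start) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14,
                                       parscale = 100))
    list(zd = fit$par, entropy = fit$value, converged = fit$convergence == 0L)
  }
  best <- run(zd_init)
  if (abs(best$zd - zd_init) < 1) {
    # flat gradient at the start: try descending from either side of the DOF
    for (start in c(zd_init + restart_offset, zd_init - restart_offset)) {
      cand <- run(start)
      if (cand$entropy < best$entropy) best <- cand
    }
  }
  pol <- stats::optimize(obj, interval = best$zd + c(-5, 5), tol = tol_um)
  if (pol$objective < best$entropy) {
    best$zd <- pol$minimum
    best$entropy <- pol$objective
  }
  best
}

#' Per-depth defocus estimates of a volume
#'
#' Splits the depth axis into blocks of `block` pixels and, for each block
#' whose mean composite intensity exceeds the noise floor by
#' `signal_db_margin` dB, estimates the defocus of the block's central en face
#' plane of one polarization channel with [estimate_defocus_plane()]. Blocks
#' below the signal margin are marked invalid.
#'
#' @param volume A [jones_volume()] (bulk-phase-corrected for measured data).
#' @param channel Length-2 integer vector `c(out_pol, in_pol)`; defocus is
#'   estimated on this single channel (default the (1,1) channel).
#' @param block Depth-block size in pixels.
#' @param signal_db_margin Signal threshold above the noise floor, dB.
#' @param pad_width,restart_offset,tol_um Passed to [estimate_defocus_plane()].
#' @return Object of class `defocus_profile`: list with `depth_index`,
#'   `depth_um`, `zd_um`, `entropy`, `valid` (signal mask), and empty fit
#'   slots (`slope`, `intercept`, ...) to be filled by [fit_defocus_linear()].
#' @export
estimate_defocus_profile <- function(volume, channel = c(1L, 1L), block = 50L,
                                     signal_db_margin = 5, pad_width = 50L,
                                     restart_offset = NULL, tol_um = 1e-3) {
  g <- volume$geometry
  block <- as.integer(block)
  if (block < 1L) stop("block must be >= 1")
  n_blocks <- g$n_z %/% block
  if (n_blocks < 1L) stop("volume shallower than one depth block")

  threshold <- volume$noise_floor * 10^(signal_db_margin / 10)
  centers <- integer(n_blocks); mean_I <- numeric(n_blocks)
  for (bk in seq_len(n_blocks)) {
    zr <- ((bk - 1L) * block + 1L):(bk * block)
    centers[bk] <- zr[1L] + block %/% 2L
    d <- volume$data[zr, , , , , drop = FALSE]
    mean_I[bk] <- mean(Mod(d)^2)
  }
  valid <- mean_I > threshold
  if (!any(valid)) stop("no depth block exceeds the signal margin")

  zd <- rep(NA_real_, n_blocks); ent <- rep(NA_real_, n_blocks)
  for (bk in which(valid)) {
    f <- enface_field(volume, centers[bk], channel[1], channel[2])
    est <- estimate_defocus_plane(f, g, pad_width = pad_width,
                                  restart_offset = restart_offset,
                                  tol_um = tol_um)
    zd[bk] <- est$zd; ent[bk] <- est$entropy
  }
  structure(list(
    depth_index = centers, depth_um = depth_um(g, centers),
    zd_um = zd, entropy = ent, valid = valid,
    slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
    dof_halfwidth = NA_real_, used = NULL, residuals = NULL
  ), class = "defocus_profile")
}

#' Linear depth fit of the defocus profile
#'
#' Fits `zd(z) = slope * z + intercept` by least squares through the valid
#' estimates lying outside the depth-of-focus band, then predicts `zd` for
#' every depth (extrapolating across the DOF band, where the entropy
#' objective is too flat for direct estimation). The DOF band is located
#' iteratively: an initial fit through all valid points predicts where
#' `|zd| < dof_halfwidth`, those points are excluded, and the line is refit.
#'
#' @param profile A `defocus_profile` from [estimate_defocus_profile()].
#' @param geometry A [scan_geometry()] (used for the default DOF half-width).
#' @param dof_halfwidth DOF half-width in um; defaults to
#'   [dof_halfwidth()] of `geometry`.
#' @return The profile with `slope` (um/um), `intercept` (um), `r_squared`
#'   (over the points used), `used` (logical mask of fitted points),
#'   `residuals`, `dof_halfwidth`, and `predict` (function of depth in um).
#' @export
fit_defocus_linear <- function(profile, geometry = NULL, dof_halfwidth = NULL) {
  if (is.null(dof_halfwidth)) {
    if (is.null(geometry)) stop("supply geometry or dof_halfwidth")
    dof_halfwidth <- jmoct::dof_halfwidth(geometry)
  }
  ok <- profile$valid & is.finite(profile$zd_um)
  if (sum(ok) < 2L)
    stop("need at least 2 valid defocus estimates; widen the volume or ",
         "supply a manual zd line")
  z <- profile$depth_um; zd <- profile$zd_um

  fit_line <- function(mask) stats::lm(zd[mask] ~ z[mask])
  used <- ok
  for (i in 1:2) {
    fit <- fit_line(used)
    co <- stats::coef(fit)
    pred_all <- co[2] * z + co[1]
    outside <- abs(pred_all) > dof_halfwidth
    cand <- ok & outside
    if (sum(cand) >= 2L && !identical(cand, used)) used <- cand else break
  }
  fit <- stats::lm(zdv ~ zv, data = data.frame(zv = z[used], zdv = zd[used]))
  co <- stats::coef(fit)
  profile$slope <- unname(co[2])
  profile$intercept <- unname(co[1])
  sst <- sum((zd[used] - mean(zd[used]))^2)
  profile$r_squared <- if (sst == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / sst
  profile$dof_halfwidth <- dof_halfwidth
  profile$used <- used
  profile$residuals <- ifelse(ok, zd - (profile$slope * z + profile$intercept),
                              NA_real_)
  profile$predict <- function(depth) profile$slope * depth + profile$intercept
  profile
}

#' Manually specified defocus line
#'
#' Builds a fitted `defocus_profile` directly from a known slope/intercept,
#' e.g. the simulator's ground truth or an operator override.
#' @param slope Defocus change per physical depth (um/um).
#' @param intercept Defocus at depth 0 (um).
#' @return A `defocus_profile` with the fit slots populated.
#' @export
manual_defocus_profile <- function(slope, intercept) {
  structure(list(
    depth_index = integer(0), depth_um = numeric(0), zd_um = numeric(0),
    entropy = numeric(0), valid = logical(0),
    slope = slope, intercept = intercept, r_squared = NA_real_,
    dof_halfwidth = NA_real_, used = logical(0), residuals = numeric(0),
    predict = function(depth) slope * depth + intercept
  ), class = "defocus_profile")
}

#' Bulk (piston) phase error correction
#'
#' Acquisition-time phase drift adds a piston phase per frame (slow-axis
#' position) that destroys the lateral phase coherence refocusing relies on.
#' The piston sequence is estimated from a single reference channel as the
#' cumulative sum of the phase of the lag-1 complex autocorrelation between
#' adjacent frames, and the *same* phase is removed from all four channels at
#' every voxel, so the relative phases between channels are untouched.
#' Frames with zero signal get zero correction.
#'
#' @param volume A [jones_volume()].
#' @param reference_channel Length-2 integer vector `c(out_pol, in_pol)`.
#' @return The corrected [jones_volume()] with `bulk_corrected = TRUE` and a
#'   `bulk_phase_estimate` field (the removed phase per frame, rad).
#' @export
bulk_phase_correct <- function(volume, reference_channel = c(1L, 1L)) {
  g <- volume$geometry
  ref <- volume$data[, , , reference_channel[1], reference_channel[2]]
  dim(ref) <- c(g$n_z, g$n_y, g$n_x)
  dphi <- numeric(g$n_y)
  for (y in seq_len(g$n_y)[-1]) {
    corr <- sum(ref[, y, ] * Conj(ref[, y - 1L, ]))
    dphi[y] <- if (Mod(corr) > 0) Arg(corr) else 0
  }
  phi <- cumsum(dphi)
  corr_factor <- exp(-(0 + 1i) * phi)
  d <- volume$data
  for (y in seq_len(g$n_y)) {
    if (phi[y] != 0) d[, y, , , ] <- d[, y, , , ] * corr_factor[y]
  }
  out <- jones_volume(d, g, bulk_corrected = TRUE, refocused = volume$refocused,
                      noise_floor = volume$noise_floor,
                      ground_truth = volume$ground_truth)
  out$bulk_phase_estimate <- phi
  out
}

#' Refocus all four polarization channels of a volume
#'
#' Applies [propagate_enface()] with the refocusing sign to every en face
#' plane of every channel, using the fitted line `zd(z)` of `profile`. At a
#' given depth the *same* filter is applied to all four channels, preserving
#' the phase consistency between them.
#'
#' @param volume A [jones_volume()].
#' @param profile A fitted `defocus_profile` ([fit_defocus_linear()] or
#'   [manual_defocus_profile()]).
#' @param pad_width Zero padding per plane.
#' @return The refocused [jones_volume()] with `refocused = TRUE`.
#' @export
refocus_volume <- function(volume, profile, pad_width = 50L) {
  if (!inherits(profile, "defocus_profile") || !is.finite(profile$slope))
    stop("profile must be a fitted defocus_profile")
  g <- volume$geometry
  zd_line <- profile$slope * depth_um(g, seq_len(g$n_z)) + profile$intercept
  d <- volume$data
  for (z in seq_len(g$n_z)) {
    if (zd_line[z] == 0) next
    for (i in 1:2) for (j in 1:2) {
      f <- matrix(d[z, , , i, j], g$n_y, g$n_x)
      d[z, , , i, j] <- propagate_enface(f, g, zd_line[z], sign = -1,
                                         pad_width = pad_width)
    }
  }
  jones_volume(d, g, bulk_corrected = volume$bulk_corrected, refocused = TRUE,
               noise_floor = volume$noise_floor,
               ground_truth = volume$ground_truth)
}
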