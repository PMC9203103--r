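#' Local Jones matrix of a depth slab
#'
#' Isolates the polarization effect of the slab between two depths by the
#' similarity construction Jl = Jm(z2) Jm(z1)^-1, evaluated per lateral pixel.
#' Jl is similar to the sample's local round-trip Jones matrix, so its
#' eigenvalue phases carry the slab's phase retardation regardless of the
#' (unknown) system matrices.
#'
#' Pixels where Jm(z1) is numerically singular (|det| below `det_tol` times
#' the plane median |det|) are flagged invalid rather than inverted.
#'
#' @param volume A [jones_volume()].
#' @param z1_index,z2_index Depth pixel indices, `z2_index > z1_index`.
#' @param det_tol Relative determinant threshold for the inversion guard.
#' @return An object of class `local_jones_field`: list with `data` (complex
#'   array `(n_y, n_x, 2, 2)`), `valid` (logical matrix), `z1_index`,
#'   `z2_index`, and `Zd` (physical separation, um).
#' @export
cumulative_to_local <- function(volume, z1_index, z2_index, det_tol = 1e-6) {
  g <- volume$geometry
  if (z1_index < 1L || z2_index > g$n_z) stop("depth indices out of range")
  if (z2_index <= z1_index) stop("z2_index must be greater than z1_index")

  d <- volume$data
  a <- matrix(d[z1_index, , , 1, 1], g$n_y, g$n_x)
  b <- matrix(d[z1_index, , , 1, 2], g$n_y, g$n_x)
  cc <- matrix(d[z1_index, , , 2, 1], g$n_y, g$n_x)
  dd <- matrix(d[z1_index, , , 2, 2], g$n_y, g$n_x)
  A <- matrix(d[z2_index, , , 1, 1], g$n_y, g$n_x)
  B <- matrix(d[z2_index, , , 1, 2], g$n_y, g$n_x)
  C <- matrix(d[z2_index, , , 2, 1], g$n_y, g$n_x)
  D <- matrix(d[z2_index, , , 2, 2], g$n_y, g$n_x)

  det1 <- a * dd - b * cc
  med <- stats::median(Mod(det1))
  valid <- Mod(det1) > det_tol * med
  if (med == 0 || !any(valid)) {
    warning("all pixels have a near-singular Jm(z1); returning empty validity")
    valid[] <- FALSE
  }

  out <- array(NA_complex_, c(g$n_y, g$n_x, 2L, 2L))
  det_safe <- ifelse(valid, det1, 1 + 0i)
  out[, , 1, 1] <- (A * dd - B * cc) / det_safe
  out[, , 1, 2] <- (-A * b + B * a) / det_safe
  out[, , 2, 1] <- (C * dd - D * cc) / det_safe
  out[, , 2, 2] <- (-C * b + D * a) / det_safe
  out[, , 1, 1][!valid] <- NA_complex_
  out[, , 1, 2][!valid] <- NA_complex_
  out[, , 2, 1][!valid] <- NA_complex_
  out[, , 2, 2][!valid] <- NA_complex_

  structure(list(
    data = out, valid = valid,
    z1_index = z1_index, z2_index = z2_index,
    Zd = (z2_index - z1_index) * g$depth_pitch
  ), class = "local_jones_field")
}

#' Local phase retardation from a local Jones field
#'
#' The phase retardation delta is the absolute phase difference between the
#' two eigenvalues of the 2 x 2 local Jones matrix, wrapped into `[0, pi]`
#' (retardation is defined up to conjugate eigenvalue ordering). Defective or
#' invalid pixels get `delta = 0` with reliability 0.
#'
#' The reliability channel is a heuristic in `[0, 1]`: the eigenvector
#' separation `1 - |<v1, v2>|` (normalized Hermitian inner product; 0 for a
#' defective matrix, 1 for orthogonal eigenvectors), optionally multiplied by
#' a signal weight `S / (S + noise_floor)` when the local signal intensity
#' `signal` is supplied.
#'
#' @param local A `local_jones_field` from [cumulative_to_local()].
#' @param signal Optional numeric matrix `(n_y, n_x)` of linear signal
#'   intensity used for the SNR reliability weight.
#' @param noise_floor Additive-noise intensity for the SNR weight.
#' @return An object of class `retardation_map`: list with `delta` (rad,
#'   `(n_y, n_x)`), `reliability`, `valid`, and `Zd` (um).
#' @export
phase_retardation <- function(local, signal = NULL, noise_floor = 0) {
  J <- local$data
  a <- J[, , 1, 1]; b <- J[, , 1, 2]; cc <- J[, , 2, 1]; d <- J[, , 2, 2]
  tr <- a + d
  det <- a * d - b * cc
  s <- sqrt(tr^2 - 4 * det)
  l1 <- (tr + s) / 2
  l2 <- (tr - s) / 2

  delta <- abs(Arg(l1 * Conj(l2)))

  # eigenvectors: (b, l - a) unless degenerate in that form, else (l - d, c)
  eigvec <- function(l) {
    v1 <- b; v2 <- l - a
    use_alt <- (Mod(v1) + Mod(v2)) < 1e-14 * (Mod(a) + Mod(d) + 1e-300)
    v1[use_alt] <- (l - d)[use_alt]
    v2[use_alt] <- cc[use_alt]
    nrm <- sqrt(Mod(v1)^2 + Mod(v2)^2)
    zero <- nrm < 1e-300
    nrm[zero] <- 1
    v1[zero] <- 1; v2[zero] <- 0   # arbitrary unit vector for the degenerate case
    list(v1 = v1 / nrm, v2 = v2 / nrm)
  }
  e1 <- eigvec(l1); e2 <- eigvec(l2)
  overlap <- Mod(Conj(e1$v1) * e2$v1 + Conj(e1$v2) * e2$v2)
  reliability <- pmin(pmax(1 - overlap, 0), 1)

  # defective / near-degenerate eigenvalues: retardation undefined -> 0, rel 0
  degen <- Mod(s) < 1e-12 * (Mod(l1) + Mod(l2) + 1e-300)
  delta[degen] <- 0
  reliability[degen] <- 0

  bad <- !local$valid | !is.finite(delta)
  delta[bad] <- 0
  reliability[bad] <- 0

  if (!is.null(signal)) {
    w <- signal / (signal + noise_floor)
    w[!is.finite(w)] <- 0
    reliability <- reliability * pmin(pmax(w, 0), 1)
  }

  structure(list(delta = delta, reliability = reliability,
                 valid = local$valid & !degen, Zd = local$Zd),
            class = "retardation_map")
}

#' Convert phase retardation to birefringence
#'
#' Birefringence is the local phase retardation normalized by twice the
#' optical round trip through the slab: b = delta / (2 k0 Zd). With
#' delta in `[0, pi]`, b lies in `[0, pi / (2 k0 Zd)]`.
#'
#' @param delta A `retardation_map` from [phase_retardation()].
#' @param Zd Slab thickness in um (defaults to the map's own `Zd`).
#' @param k0 Center wavenumber in rad/um.
#' @return An object of class `birefringence_map`: list with `b`
#'   (dimensionless refractive-index units), `reliability`, `valid`, `Zd`.
#' @export
retardation_to_birefringence <- function(delta, Zd = delta$Zd, k0) {
  if (is.null(Zd) || Zd <= 0) stop("Zd must be strictly positive")
  if (k0 <= 0) stop("k0 must be strictly positive")
  structure(list(b = delta$delta / (2 * k0 * Zd),
                 reliability = delta$reliability,
                 valid = delta$valid, Zd = Zd),
            class = "birefringence_map")
}

#' Depth-resolved birefringence of a volume
#'
#' Slides a depth window of `Zd_pixels` pixels through the volume: at each
#' output depth z the local Jones matrix over `[z, z + Zd_pixels)` is formed,
#' its eigenvalue phase retardation extracted, and converted to birefringence
#' with Zd = `Zd_pixels` x depth pitch. The output depth range is truncated to
#' windows that fit inside the volume.
#'
#' @param volume A [jones_volume()].
#' @param Zd_pixels Depth-window size in pixels (default 8; 57.9 um at a
#'   7.24 um depth pitch).
#' @param det_tol Inversion guard passed to [cumulative_to_local()].
#' @return List of class `birefringence_volume` with `b` and `reliability`
#'   arrays `(n_z - Zd_pixels, n_y, n_x)`, `valid`, `depth_indices`, `Zd` (um).
#' @export
birefringence_map <- function(volume, Zd_pixels = 8L, det_tol = 1e-6) {
  g <- volume$geometry
  Zd_pixels <- as.integer(Zd_pixels)
  if (Zd_pixels < 1L) stop("Zd_pixels must be >= 1")
  if (g$n_z <= Zd_pixels)
    stop("volume has too few depth pixels for a ", Zd_pixels, "-pixel window")
  n_out <- g$n_z - Zd_pixels
  b <- array(0, c(n_out, g$n_y, g$n_x))
  rel <- array(0, c(n_out, g$n_y, g$n_x))
  valid <- array(FALSE, c(n_out, g$n_y, g$n_x))
  I <- intensity_composite(volume)
  for (z in seq_len(n_out)) {
    loc <- cumulative_to_local(volume, z, z + Zd_pixels, det_tol = det_tol)
    sig <- matrix(colMeans(matrix(I[z:(z + Zd_pixels), , ],
                                  Zd_pixels + 1L, g$n_y * g$n_x)),
                  g$n_y, g$n_x)
    ret <- phase_retardation(loc, signal = sig, noise_floor = volume$noise_floor)
    bm <- retardation_to_birefringence(ret, k0 = g$k0)
    b[z, , ] <- bm$b
    rel[z, , ] <- bm$reliability
    valid[z, , ] <- bm$valid
  }
  structure(list(b = b, reliability = rel, valid = valid,
                 depth_indices = seq_len(n_out),
                 Zd = Zd_pixels * g$depth_pitch, Zd_pixels = Zd_pixels),
            class = "birefringence_volume")
}
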