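#' Scan geometry of a JM-OCT acquisition
#'
#' Describes the sampling grid of a Jones-matrix OCT volume: pixel counts,
#' lateral pixel separation (pitch), depth pixel separation in tissue, the
#' probe center wavelength, and the system's lateral resolution. The lateral
#' pitch can be given directly in micrometres per pixel, or derived from a
#' physical scan range in millimetres (pitch = range / n), mirroring how scan
#' protocols are usually reported (e.g. 512 A-lines over 3 mm).
#'
#' @param n_x,n_y,n_z Pixel counts along the fast lateral, slow lateral, and
#'   depth axes.
#' @param lateral_pitch_x,lateral_pitch_y Lateral pixel separation in um/pixel.
#'   `lateral_pitch_y` defaults to `lateral_pitch_x` (isotropic raster scan).
#' @param lateral_range_x,lateral_range_y Physical lateral extent in mm.
#'   Used to derive the pitch when the pitch is not given; when both are given
#'   they must agree to within 0.005 um.
#' @param depth_pitch Depth pixel separation in tissue, um/pixel.
#' @param center_wavelength Probe center wavelength lambda_c in um. The
#'   wavenumber is k0 = 2 pi / lambda_c.
#' @param lateral_resolution Lateral resolution (FWHM) of the system in um.
#'   Used to derive the beam waist and depth-of-focus band.
#'
#' @return An object of class `scan_geometry`: a list with fields `n_x`,
#'   `n_y`, `n_z`, `lateral_pitch_x`, `lateral_pitch_y`, `lateral_range_x`,
#'   `lateral_range_y` (mm), `depth_pitch`, `center_wavelength`, `k0`
#'   (rad/um), and `lateral_resolution`.
#' @examples
#' g <- scan_geometry(512, 512, 128, lateral_range_x = 3)
#' g$lateral_pitch_x  # 5.86 um
#' @export
scan_geometry <- function(n_x, n_y, n_z,
                          lateral_pitch_x = NULL, lateral_pitch_y = NULL,
                          lateral_range_x = NULL, lateral_range_y = NULL,
                          depth_pitch = 7.24,
                          center_wavelength = 1.31,
                          lateral_resolution = 18) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y); n_z <- as.integer(n_z)
  if (any(c(n_x, n_y, n_z) < 1L)) stop("pixel counts must be >= 1")
  if (depth_pitch <= 0) stop("depth_pitch must be strictly positive")
  if (center_wavelength <= 0) stop("center_wavelength must be strictly positive")
  if (lateral_resolution <= 0) stop("lateral_resolution must be strictly positive")

  resolve_axis <- function(pitch, range_mm, n, axis) {
    if (is.null(pitch) && is.null(range_mm))
      stop("provide lateral pitch or range for axis ", axis)
    if (is.null(pitch)) pitch <- range_mm * 1000 / n
    if (!is.null(range_mm) &&
        abs(pitch - range_mm * 1000 / n) > 0.005)
      stop("lateral pitch and range disagree on axis ", axis,
           " (|pitch - range/n| > 0.005 um)")
    if (pitch <= 0) stop("lateral pitch must be strictly positive on axis ", axis)
    pitch
  }
  if (is.null(lateral_pitch_y) && is.null(lateral_range_y)) {
    lateral_pitch_y <- if (is.null(lateral_pitch_x))
      resolve_axis(NULL, lateral_range_x, n_y, "y") else lateral_pitch_x
  }
  px <- resolve_axis(lateral_pitch_x, lateral_range_x, n_x, "x")
  py <- resolve_axis(lateral_pitch_y, lateral_range_y, n_y, "y")

  structure(list(
    n_x = n_x, n_y = n_y, n_z = n_z,
    lateral_pitch_x = px, lateral_pitch_y = py,
    lateral_range_x = px * n_x / 1000, lateral_range_y = py * n_y / 1000,
    depth_pitch = depth_pitch,
    center_wavelength = center_wavelength,
    k0 = 2 * pi / center_wavelength,
    lateral_resolution = lateral_resolution
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("JM-OCT scan geometry: %d x %d A-lines x %d depth pixels\n",
              x$n_x, x$n_y, x$n_z))
  cat(sprintf("  lateral pitch : %.4g x %.4g um (%.3g x %.3g mm range)\n",
              x$lateral_pitch_x, x$lateral_pitch_y,
              x$lateral_range_x, x$lateral_range_y))
  cat(sprintf("  depth pitch   : %.4g um  |  lambda_c %.4g um (k0 = %.4g rad/um)\n",
              x$depth_pitch, x$center_wavelength, x$k0))
  cat(sprintf("  lateral res.  : %.4g um FWHM (DOF half-width %.4g um)\n",
              x$lateral_resolution, dof_halfwidth(x)))
  invisible(x)
}

#' Physical depth (um) of a depth pixel index
#'
#' Depth index 1 is the shallowest plane at depth 0.
#' @param geometry A [scan_geometry()].
#' @param z_index Depth pixel index (1-based), possibly a vector.
#' @return Depth in um.
#' @export
depth_um <- function(geometry, z_index) (z_index - 1) * geometry$depth_pitch

#' Gaussian beam waist implied by the lateral resolution
#'
#' Converts the lateral FWHM resolution to the 1/e^2 intensity beam-waist
#' radius, w0 = FWHM / sqrt(2 ln 2).
#' @param geometry A [scan_geometry()].
#' @return Beam waist w0 in um.
#' @export
beam_waist <- function(geometry) {
  geometry$lateral_resolution / sqrt(2 * log(2))
}

#' Depth-of-focus half-width (Rayleigh range)
#'
#' zR = pi w0^2 / lambda_c, with w0 from [beam_waist()]. Within +/- zR of the
#' focus the Fresnel phase filter is a very weak quadratic phase and
#' entropy-based defocus estimation is unreliable; estimates there are
#' replaced by linear extrapolation.
#' @param geometry A [scan_geometry()].
#' @return DOF half-width in um.
#' @export
dof_halfwidth <- function(geometry) {
  w0 <- beam_waist(geometry)
  pi * w0^2 / geometry$center_wavelength
}

# Unshifted DFT frequencies in cycles/um for n samples at `pitch` um/pixel;
# zero-frequency bin at index 1.
dft_freqs <- function(n, pitch) {
  if (pitch <= 0) stop("pitch must be strictly positive")
  if (n == 1L) return(0)
  k <- 0:(n - 1)
  k[k > (n - 1) %/% 2] <- k[k > (n - 1) %/% 2] - n
  k / (n * pitch)
}
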