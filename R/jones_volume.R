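#' Four-channel complex JM-OCT volume
#'
#' The central container of the package: the cumulative measured Jones matrix
#' Jm(x, y, z) sampled on the scan grid. `data` is a complex array indexed
#' `[z, y, x, out_pol, in_pol]`; the four polarization channels are the 2 x 2
#' matrix entries measured by polarization-multiplexed illumination (columns,
#' `in_pol`) and polarization-diversity detection (rows, `out_pol`).
#'
#' @param data Complex array of shape `(n_z, n_y, n_x, 2, 2)`.
#' @param geometry A [scan_geometry()] consistent with `dim(data)`.
#' @param bulk_corrected Logical provenance flag: has the per-frame bulk phase
#'   error been removed (see [bulk_phase_correct()])?
#' @param refocused Logical provenance flag: has the volume been refocused
#'   (see [refocus_volume()])?
#' @param noise_floor Additive complex-noise variance per channel, in linear
#'   intensity units (E|n|^2). Zero for noise-free synthetic data.
#' @param ground_truth Optional list of simulator ground truth (see
#'   [simulate_jones_volume()]); `NULL` for measured data.
#'
#' @return An object of class `jones_volume`.
#' @export
jones_volume <- function(data, geometry, bulk_corrected = FALSE,
                         refocused = FALSE, noise_floor = 0,
                         ground_truth = NULL) {
  if (!is.complex(data)) data <- data + 0i
  expected <- c(geometry$n_z, geometry$n_y, geometry$n_x, 2L, 2L)
  if (!identical(as.integer(dim(data)), as.integer(expected)))
    stop("data shape ", paste(dim(data), collapse = "x"),
         " does not match geometry (expected ",
         paste(expected, collapse = "x"), ")")
  if (anyNA(data) || any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("volume entries must all be finite")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  structure(list(
    data = data, geometry = geometry,
    bulk_corrected = isTRUE(bulk_corrected),
    refocused = isTRUE(refocused),
    noise_floor = noise_floor,
    ground_truth = ground_truth
  ), class = "jones_volume")
}

#' @export
print.jones_volume <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("JM-OCT Jones volume: %d x %d x %d voxels x 4 channels\n",
              g$n_z, g$n_y, g$n_x))
  cat(sprintf("  bulk corrected: %s | refocused: %s | noise floor: %.3g\n",
              x$bulk_corrected, x$refocused, x$noise_floor))
  if (!is.null(x$ground_truth)) cat("  carries simulator ground truth\n")
  invisible(x)
}

#' Extract one en face complex plane of one polarization channel
#'
#' @param volume A [jones_volume()].
#' @param z_index Depth pixel index (1-based).
#' @param out_pol,in_pol Channel indices in 1:2 (detection row, input column).
#' @return Complex matrix of shape `(n_y, n_x)`.
#' @export
enface_field <- function(volume, z_index, out_pol = 1L, in_pol = 1L) {
  g <- volume$geometry
  if (z_index < 1L || z_index > g$n_z) stop("z_index out of range")
  matrix(volume$data[z_index, , , out_pol, in_pol], g$n_y, g$n_x)
}

#' Composite OCT intensity
#'
#' The intensity OCT image is the pixelwise average of the four polarization
#' channels' intensities, |Jm_ij|^2.
#'
#' @param volume A [jones_volume()].
#' @return Numeric array `(n_z, n_y, n_x)` of linear intensity.
#' @export
intensity_composite <- function(volume) {
  d <- volume$data
  (Mod(d[, , , 1, 1, drop = FALSE])^2 + Mod(d[, , , 1, 2, drop = FALSE])^2 +
   Mod(d[, , , 2, 1, drop = FALSE])^2 + Mod(d[, , , 2, 2, drop = FALSE])^2) / 4 ->
    s
  array(s, dim = dim(d)[1:3])
}
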