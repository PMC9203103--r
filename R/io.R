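#' Write a Jones volume to a hierarchical directory container
#'
#' The container is a directory holding `meta.json` (geometry attributes,
#' provenance flags, noise floor), the complex Jones data as paired
#' little-endian float64 arrays `jones_real.bin` / `jones_imag.bin` (stored
#' real/imaginary for portability across readers), and, for synthetic
#' volumes, a `ground_truth/` subgroup (true birefringence and axis maps,
#' defocus line, injected bulk phases). Writing then reading reproduces the
#' volume bit-exactly.
#'
#' @param volume A [jones_volume()].
#' @param path Container directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- volume$geometry
  meta <- list(
    format = "jmoct-volume", format_version = 1L,
    dims = as.integer(dim(volume$data)),
    n_x = g$n_x, n_y = g$n_y, n_z = g$n_z,
    lateral_pitch_x = g$lateral_pitch_x, lateral_pitch_y = g$lateral_pitch_y,
    depth_pitch = g$depth_pitch, center_wavelength = g$center_wavelength,
    lateral_resolution = g$lateral_resolution,
    bulk_corrected = volume$bulk_corrected, refocused = volume$refocused,
    noise_floor = volume$noise_floor,
    has_ground_truth = !is.null(volume$ground_truth)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  write_f64 <- function(x, file) {
    con <- file(file, "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  write_f64(Re(volume$data), file.path(path, "jones_real.bin"))
  write_f64(Im(volume$data), file.path(path, "jones_imag.bin"))
  gt <- volume$ground_truth
  if (!is.null(gt)) {
    gdir <- file.path(path, "ground_truth")
    dir.create(gdir, showWarnings = FALSE)
    scalars <- gt[!vapply(gt, function(x)
      is.array(x) || length(x) > 1L, logical(1))]
    jsonlite::write_json(scalars, file.path(gdir, "scalars.json"),
                         auto_unbox = TRUE, digits = I(17))
    if (!is.null(gt$b_true)) write_f64(gt$b_true, file.path(gdir, "b_true.bin"))
    if (!is.null(gt$theta)) write_f64(gt$theta, file.path(gdir, "theta.bin"))
    if (!is.null(gt$injected_phases))
      write_f64(gt$injected_phases, file.path(gdir, "injected_phases.bin"))
  }
  invisible(path)
}

#' Read a Jones volume from a directory container
#'
#' @param path Container directory written by [write_volume()].
#' @return A [jones_volume()] (with ground truth when the container carries
#'   it).
#' @export
read_volume <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a volume container: missing meta.json in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("dims", "n_x", "n_y", "n_z", "lateral_pitch_x",
                "lateral_pitch_y", "depth_pitch", "center_wavelength")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    stop("volume container lacks required attribute(s): ",
         paste(missing, collapse = ", "))
  g <- scan_geometry(meta$n_x, meta$n_y, meta$n_z,
                     lateral_pitch_x = meta$lateral_pitch_x,
                     lateral_pitch_y = meta$lateral_pitch_y,
                     depth_pitch = meta$depth_pitch,
                     center_wavelength = meta$center_wavelength,
                     lateral_resolution =
                       if (is.null(meta$lateral_resolution)) 18
                       else meta$lateral_resolution)
  read_f64 <- function(file, n) {
    if (!file.exists(file)) stop("volume container corrupt: missing ", file)
    con <- file(file, "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    if (length(x) != n) stop("volume container corrupt: truncated ", file)
    x
  }
  n <- prod(meta$dims)
  re <- read_f64(file.path(path, "jones_real.bin"), n)
  im <- read_f64(file.path(path, "jones_imag.bin"), n)
  data <- array(complex(real = re, imaginary = im), meta$dims)
  gt <- NULL
  gdir <- file.path(path, "ground_truth")
  if (isTRUE(meta$has_ground_truth) && dir.exists(gdir)) {
    gt <- jsonlite::read_json(file.path(gdir, "scalars.json"),
                              simplifyVector = TRUE)
    map_dims <- meta$dims[1:3]
    if (file.exists(file.path(gdir, "b_true.bin")))
      gt$b_true <- array(read_f64(file.path(gdir, "b_true.bin"),
                                  prod(map_dims)), map_dims)
    if (file.exists(file.path(gdir, "theta.bin")))
      gt$theta <- array(read_f64(file.path(gdir, "theta.bin"),
                                 prod(map_dims)), map_dims)
    pf <- file.path(gdir, "injected_phases.bin")
    if (file.exists(pf)) gt$injected_phases <- read_f64(pf, meta$dims[2])
  }
  jones_volume(data, g, bulk_corrected = isTRUE(meta$bulk_corrected),
               refocused = isTRUE(meta$refocused),
               noise_floor = meta$noise_floor, ground_truth = gt)
}

#' Export a contrast map or pseudo-colour composite to an image file
#'
#' Pseudo-colour composites are written as 8-bit PNG; scalar maps either as
#' windowed 8-bit grayscale PNG (`kind = "intensity"`, dB windowing) or as a
#' single-channel 32-bit floating-point TIFF (`kind = "map"`, values scaled
#' by a recorded factor into [0, 1]). Every export writes a JSON sidecar
#' (`<path>.json`) with the windowing/scaling parameters so the rendering is
#' reproducible.
#'
#' @param x A `pseudo_color_image`, or a numeric matrix.
#' @param kind `"rgb"`, `"intensity"`, or `"map"`.
#' @param path Output file path (`.png` for rgb/intensity, `.tif` for map).
#' @param db_window Intensity display window in dB for `kind = "intensity"`.
#' @return `path`, invisibly.
#' @export
export_image <- function(x, kind = c("rgb", "intensity", "map"), path,
                         db_window = NULL) {
  kind <- match.arg(kind)
  sidecar <- paste0(path, ".json")
  if (kind == "rgb") {
    if (!inherits(x, "pseudo_color_image"))
      stop("kind 'rgb' needs a pseudo_color_image")
    png::writePNG(x$rgb, path)
    jsonlite::write_json(list(kind = x$kind, hue_range = x$hue_range,
                              hue_span = x$hue_span, db_window = x$db_window),
                         sidecar, auto_unbox = TRUE, digits = I(17))
  } else if (kind == "intensity") {
    if (!is.matrix(x)) stop("kind 'intensity' needs a numeric matrix")
    sc <- db_scale(x, db_window)
    png::writePNG(sc$v, path)
    jsonlite::write_json(list(kind = "intensity", db_window = sc$db_window),
                         sidecar, auto_unbox = TRUE, digits = I(17))
  } else {
    if (!is.matrix(x)) stop("kind 'map' needs a numeric matrix")
    mx <- max(x, na.rm = TRUE)
    scale <- if (mx > 0) mx else 1
    m <- x / scale
    m[!is.finite(m)] <- 0
    tiff::writeTIFF(pmin(pmax(m, 0), 1), path, bits.per.sample = 32L)
    jsonlite::write_json(list(kind = "map", value_scale = scale),
                         sidecar, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}
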