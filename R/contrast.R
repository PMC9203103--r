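#' Stokes vectors of the two input polarization states
#'
#' For each input state (column of the measured Jones matrix) the two
#' detection-channel amplitudes `(E1, E2)` define the Stokes parameters
#' `S0 = |E1|^2 + |E2|^2`, `S1 = |E1|^2 - |E2|^2`, `S2 = 2 Re(E1 E2*)`,
#' `S3 = -2 Im(E1 E2*)`. Before any spatial averaging each voxel is fully
#' polarized: `S0^2 = S1^2 + S2^2 + S3^2`.
#'
#' @param volume A [jones_volume()].
#' @return Object of class `stokes_field`: list with arrays `S0`, `S1`, `S2`,
#'   `S3` of shape `(n_z, n_y, n_x, 2)` (last index = input state) and
#'   `noise_variance` (per detection channel, from the volume's noise floor).
#' @export
jones_to_stokes <- function(volume) {
  g <- volume$geometry
  dims <- c(g$n_z, g$n_y, g$n_x, 2L)
  S0 <- array(0, dims); S1 <- array(0, dims)
  S2 <- array(0, dims); S3 <- array(0, dims)
  for (s in 1:2) {
    E1 <- volume$data[, , , 1, s]
    E2 <- volume$data[, , , 2, s]
    cross <- E1 * Conj(E2)
    S0[, , , s] <- Mod(E1)^2 + Mod(E2)^2
    S1[, , , s] <- Mod(E1)^2 - Mod(E2)^2
    S2[, , , s] <- 2 * Re(cross)
    S3[, , , s] <- -2 * Im(cross)
  }
  structure(list(S0 = S0, S1 = S1, S2 = S2, S3 = S3,
                 noise_variance = volume$noise_floor),
            class = "stokes_field")
}

# Kernel (box) mean of a matrix; only full-kernel interior pixels are valid,
# edge pixels are NA.
box_mean <- function(m, ky, kx) {
  ny <- nrow(m); nx <- ncol(m)
  if (ky > ny || kx > nx) stop("kernel larger than the field")
  # summed-area table with a zero border
  sat <- rbind(0, apply(m, 2, cumsum))
  sat <- cbind(0, t(apply(sat, 1, cumsum)))
  oy <- ny - ky + 1L; ox <- nx - kx + 1L
  sums <- sat[(ky + 1):(ny + 1), (kx + 1):(nx + 1), drop = FALSE] -
    sat[1:oy, (kx + 1):(nx + 1), drop = FALSE] -
    sat[(ky + 1):(ny + 1), 1:ox, drop = FALSE] +
    sat[1:oy, 1:ox, drop = FALSE]
  out <- matrix(NA_real_, ny, nx)
  y0 <- (ky - 1L) %/% 2L; x0 <- (kx - 1L) %/% 2L
  out[y0 + seq_len(oy), x0 + seq_len(ox)] <- sums / (ky * kx)
  out
}

#' Degree of polarization uniformity (DOPU) with noise correction
#'
#' DOPU measures the spatial uniformity of the polarization state: for each
#' input state the Stokes parameters are averaged over a small en face kernel,
#' the norm of the averaged `(S1, S2, S3)` is normalized by the averaged `S0`,
#' and the two input states' values are combined by `S0`-weighted summation.
#' Uniform fully-polarized regions give DOPU = 1; polarization-scrambling
#' regions give low DOPU.
#'
#' Additive detector noise biases DOPU low. The correction subtracts the known
#' additive-noise contribution from the averaged `S0`
#' (`<S0> - 2 sigma^2`) and the noise-induced bias of each squared
#' kernel-mean Stokes norm (`<Si>^2 - (2 sigma^2 S0 + 2 sigma^4)/N`),
#' clamping negative values to zero; the noise variance per detection channel
#' is taken from the Stokes field (the simulator records it; for measured data
#' it comes from a noise-floor measurement).
#'
#' @param stokes A `stokes_field` from [jones_to_stokes()].
#' @param kernel Kernel size `c(ky, kx)` in en face pixels (default 3 x 3).
#' @param corrected Apply the noise correction (`TRUE`) or plain averaging.
#' @param noise_variance Override of the per-channel noise variance.
#' @return Object of class `dopu_map`: list with `dopu` array
#'   `(n_z, n_y, n_x)` clamped to `[0, 1]`, `raw` (pre-clamp values), `valid`
#'   (interior pixels with usable signal), and `kernel`.
#' @export
compute_dopu <- function(stokes, kernel = c(3L, 3L), corrected = TRUE,
                         noise_variance = NULL) {
  if (is.null(noise_variance)) noise_variance <- stokes$noise_variance
  if (!corrected) noise_variance <- 0
  sig2 <- noise_variance
  dims <- dim(stokes$S0)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  ky <- as.integer(kernel[1]); kx <- as.integer(kernel[2])
  if (ky > ny || kx > nx) stop("kernel larger than the field")
  N <- ky * kx
  dopu <- array(NA_real_, c(nz, ny, nx))
  raw <- array(NA_real_, c(nz, ny, nx))
  valid <- array(FALSE, c(nz, ny, nx))
  eps <- .Machine$double.eps
  for (z in seq_len(nz)) {
    num_w <- matrix(0, ny, nx); den_w <- matrix(0, ny, nx)
    for (s in 1:2) {
      m0 <- box_mean(matrix(stokes$S0[z, , , s], ny, nx), ky, kx)
      m1 <- box_mean(matrix(stokes$S1[z, , , s], ny, nx), ky, kx)
      m2 <- box_mean(matrix(stokes$S2[z, , , s], ny, nx), ky, kx)
      m3 <- box_mean(matrix(stokes$S3[z, , , s], ny, nx), ky, kx)
      s0c <- pmax(m0 - 2 * sig2, 0)
      bias <- (2 * sig2 * s0c + 2 * sig2^2) / N
      nrm <- sqrt(pmax(m1^2 - bias, 0) + pmax(m2^2 - bias, 0) +
                  pmax(m3^2 - bias, 0))
      d_s <- nrm / pmax(s0c, eps)
      num_w <- num_w + s0c * d_s
      den_w <- den_w + s0c
    }
    r <- num_w / pmax(den_w, eps)
    raw[z, , ] <- r
    dopu[z, , ] <- pmin(pmax(r, 0), 1)
    valid[z, , ] <- is.finite(r) & den_w > eps
  }
  dopu[!valid] <- NA_real_
  structure(list(dopu = dopu, raw = raw, valid = valid,
                 kernel = c(ky, kx), corrected = corrected),
            class = "dopu_map")
}

# --- colour-space helpers -------------------------------------------------

rgb_to_hsl <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- numeric(length(r))
  idx <- d > 0 & mx == r
  h[idx] <- (((g - b) / d)[idx] / 6) %% 1
  idx <- d > 0 & mx == g & mx != r
  h[idx] <- (((b - r) / d)[idx] + 2) / 6
  idx <- d > 0 & mx == b & mx != r & mx != g
  h[idx] <- (((r - g) / d)[idx] + 4) / 6
  list(h = h, s = pmin(pmax(s, 0), 1), l = l)
}

hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 1) * 6
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- l - c_ / 2
  r <- numeric(length(h)); g <- numeric(length(h)); b <- numeric(length(h))
  seg <- floor(hp) %% 6
  r[seg == 0] <- c_[seg == 0]; g[seg == 0] <- x[seg == 0]
  r[seg == 1] <- x[seg == 1];  g[seg == 1] <- c_[seg == 1]
  g[seg == 2] <- c_[seg == 2]; b[seg == 2] <- x[seg == 2]
  g[seg == 3] <- x[seg == 3];  b[seg == 3] <- c_[seg == 3]
  r[seg == 4] <- x[seg == 4];  b[seg == 4] <- c_[seg == 4]
  r[seg == 5] <- c_[seg == 5]; b[seg == 5] <- x[seg == 5]
  list(r = pmin(pmax(r + m, 0), 1), g = pmin(pmax(g + m, 0), 1),
       b = pmin(pmax(b + m, 0), 1))
}

db_scale <- function(intensity, db_window = NULL) {
  idb <- 10 * log10(pmax(intensity, .Machine$double.xmin))
  if (is.null(db_window)) db_window <- c(max(idb) - 40, max(idb))
  v <- (idb - db_window[1]) / (db_window[2] - db_window[1])
  list(v = pmin(pmax(v, 0), 1), db_window = db_window)
}

#' Pseudo-colour birefringence composite
#'
#' HSV composition of a birefringence en face map with the OCT intensity:
#' hue encodes birefringence over `hue_range` (linear map onto a fraction
#' `hue_span` of the colour circle), saturation is the estimation
#' reliability, and value is the log-scaled intensity clipped to `db_window`.
#' With reliability 0 everywhere the image is grayscale.
#'
#' @param b Numeric matrix of birefringence, or a `birefringence_map`.
#' @param intensity Numeric matrix of linear intensity, same shape.
#' @param reliability Numeric matrix in `[0, 1]`; defaults to the map's own
#'   reliability channel, else 1.
#' @param hue_range Birefringence window mapped onto the hue axis
#'   (default `c(0, 8e-3)`).
#' @param hue_span Fraction of the hue circle used (default 2/3: red to blue).
#' @param db_window Intensity display window in dB; default upper 40 dB.
#' @return Object of class `pseudo_color_image`: list with `rgb` array
#'   `(n_y, n_x, 3)` in `[0, 1]` and the mapping parameters.
#' @export
pseudo_color_birefringence <- function(b, intensity, reliability = NULL,
                                       hue_range = c(0, 8e-3), hue_span = 2 / 3,
                                       db_window = NULL) {
  if (inherits(b, "birefringence_map")) {
    if (is.null(reliability)) reliability <- b$reliability
    b <- b$b
  }
  if (is.null(reliability)) reliability <- array(1, dim(b))
  if (!all(dim(b) == dim(intensity))) stop("map and intensity shapes differ")
  if (!all(dim(b) == dim(reliability))) stop("map and reliability shapes differ")
  hfrac <- pmin(pmax((b - hue_range[1]) / diff(hue_range), 0), 1)
  hue <- hfrac * hue_span
  sat <- pmin(pmax(reliability, 0), 1)
  val <- db_scale(intensity, db_window)
  col <- grDevices::hsv(hue, sat, val$v)
  rgbm <- grDevices::col2rgb(col) / 255
  out <- array(0, c(nrow(b), ncol(b), 3L))
  out[, , 1] <- rgbm[1, ]; out[, , 2] <- rgbm[2, ]; out[, , 3] <- rgbm[3, ]
  structure(list(rgb = out, kind = "birefringence", hue_range = hue_range,
                 hue_span = hue_span, db_window = val$db_window),
            class = "pseudo_color_image")
}

#' Pseudo-colour DOPU composite
#'
#' DOPU is mapped through a perceptually ordered rainbow (high DOPU red, low
#' DOPU yellow), the coloured image is converted to hue-saturation-lightness
#' space, and the saturation channel is replaced by the normalized log-scale
#' OCT intensity, so low-intensity regions render gray regardless of DOPU.
#'
#' @param dopu Numeric matrix of DOPU in `[0, 1]`, or a `dopu_map` plane.
#' @param intensity Numeric matrix of linear intensity, same shape.
#' @param db_window Intensity window in dB; default upper 40 dB.
#' @param hue_high,hue_low Hue (fraction of the circle) at DOPU = 1 and 0
#'   (defaults: red 0 and yellow 1/6).
#' @return A `pseudo_color_image` (see [pseudo_color_birefringence()]).
#' @export
pseudo_color_dopu <- function(dopu, intensity, db_window = NULL,
                              hue_high = 0, hue_low = 1 / 6) {
  if (!all(dim(dopu) == dim(intensity))) stop("map and intensity shapes differ")
  dv <- pmin(pmax(dopu, 0), 1)
  dv[!is.finite(dv)] <- 0
  hue <- hue_low + (hue_high - hue_low) * dv
  base <- grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255
  hsl <- rgb_to_hsl(base[1, ], base[2, ], base[3, ])
  val <- db_scale(intensity, db_window)
  rgb2 <- hsl_to_rgb(hsl$h, as.numeric(val$v), hsl$l)
  out <- array(0, c(nrow(dopu), ncol(dopu), 3L))
  out[, , 1] <- rgb2$r; out[, , 2] <- rgb2$g; out[, , 3] <- rgb2$b
  structure(list(rgb = out, kind = "dopu", hue_range = c(0, 1),
                 hue_span = hue_low - hue_high, db_window = val$db_window),
            class = "pseudo_color_image")
}
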