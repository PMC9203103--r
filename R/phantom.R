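#' Elementary Jones matrices
#'
#' `jones_rotator(theta)` is the rotation matrix R(theta);
#' `jones_retarder(delta, theta)` a linear retarder with retardation `delta`
#' (rad) and fast-axis angle `theta`: R(theta) diag(e^{i delta/2},
#' e^{-i delta/2}) R(-theta). Both are unitary.
#'
#' @param theta Axis angle in rad.
#' @param delta Retardation in rad.
#' @return Complex 2 x 2 matrix.
#' @export
jones_rotator <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2) + 0i
}

#' @rdname jones_rotator
#' @export
jones_retarder <- function(delta, theta = 0) {
  jones_rotator(theta) %*% diag(exp(c(1i, -1i) * delta / 2)) %*%
    jones_rotator(-theta)
}

#' Synthetic JM-OCT phantom description
#'
#' Describes a numerical sample with known ground truth: sparse random
#' scatterers (speckle), layered linear-retarder regions with per-voxel optic
#' axis `theta` and true birefringence `b_true`, fixed system polarization
#' matrices `Jin`/`Jout`, a Gaussian-beam focus with depth-linear defocus, and
#' additive circular complex noise.
#'
#' Scatterers are modelled as one Bernoulli(`scatterer_density`) occupancy per
#' voxel times a circular complex Gaussian amplitude: sparse occupancy
#' emulates particle phantoms and structured tissue (which is what
#' entropy-based autofocus needs), while `scatterer_density = 1` produces
#' fully developed speckle.
#'
#' @param geometry A [scan_geometry()].
#' @param focus_depth Focus depth in um from the first depth pixel. The
#'   forward defocus applied to the plane at depth z is `zd(z) = z -
#'   focus_depth`.
#' @param scatterer_density Probability that a voxel holds a scatterer.
#' @param amplitude_scale Scatterer amplitude scale (complex Gaussian sd per
#'   quadrature is `amplitude_scale / sqrt(2)`).
#' @param regions List of regions, each a list with `mask` (logical array
#'   `(n_z, n_y, n_x)` or a `function(geometry)` returning one), `theta`
#'   (rad), `b` (true birefringence, >= 0), and optional `amplitude`
#'   (relative scattering amplitude, default 1).
#' @param background_b,background_theta Birefringence and axis outside all
#'   regions.
#' @param Jin,Jout System Jones matrices (must be invertible).
#' @param noise_variance Additive complex-noise variance per channel
#'   (E|n|^2, linear intensity). Ignored when `snr_db` is given.
#' @param snr_db If non-`NULL`, the noise variance is chosen at simulation
#'   time so that mean signal intensity / noise variance equals this SNR.
#' @param confocal If `TRUE`, each en face plane's spectrum is additionally
#'   apodized by the Gaussian round-trip beam envelope
#'   `exp(-(pi w0 f)^2 / 2)` (w0 from [beam_waist()]); this band-limits the
#'   field like a real confocal OCT point-spread function and makes the
#'   entropy objective flat inside the depth of focus. With `FALSE` the
#'   forward model is the pure Fresnel phase filter, whose inverse is exact.
#' @param seed Base RNG seed for the scatterer draw.
#' @return Object of class `phantom_model` (with precomputed `b_map`,
#'   `theta_map`, `amp_map` arrays).
#' @export
phantom_model <- function(geometry, focus_depth,
                          scatterer_density = 0.05, amplitude_scale = 1,
                          regions = list(),
                          background_b = 0, background_theta = 0,
                          Jin = jones_retarder(0.9, 0.35),
                          Jout = jones_retarder(1.3, -0.5) %*% jones_rotator(0.3),
                          noise_variance = 0, snr_db = NULL,
                          confocal = FALSE, seed = 1L) {
  g <- geometry
  if (scatterer_density <= 0 || scatterer_density > 1)
    stop("scatterer_density must be in (0, 1]")
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (Mod(det2(Jin)) < 1e-12 || Mod(det2(Jout)) < 1e-12)
    stop("Jin and Jout must be invertible")
  dims <- c(g$n_z, g$n_y, g$n_x)
  b_map <- array(background_b, dims)
  theta_map <- array(background_theta, dims)
  amp_map <- array(1, dims)
  for (r in regions) {
    mask <- if (is.function(r$mask)) r$mask(g) else r$mask
    if (!identical(dim(mask), as.integer(dims)))
      stop("region mask shape does not match geometry")
    if (r$b < 0) stop("region b_true must be >= 0")
    b_map[mask] <- r$b
    theta_map[mask] <- r$theta
    if (!is.null(r$amplitude)) amp_map[mask] <- r$amplitude
  }
  structure(list(
    geometry = g, focus_depth = focus_depth,
    scatterer_density = scatterer_density, amplitude_scale = amplitude_scale,
    b_map = b_map, theta_map = theta_map, amp_map = amp_map,
    Jin = Jin, Jout = Jout,
    noise_variance = noise_variance, snr_db = snr_db,
    confocal = confocal, seed = as.integer(seed)
  ), class = "phantom_model")
}

# one-way linear-retarder layer matrices for one depth plane, elementwise
# over (n_y, n_x); eigenphases +/- k0 b dz / 2 so that the one-way
# retardation over dz is k0 b dz and the round trip accumulates 2 k0 b dz,
# which Eq.-style b = delta / (2 k0 Zd) inverts exactly.
layer_components <- function(b, theta, k0, dz) {
  phi <- k0 * b * dz / 2
  e <- exp(1i * phi); ec <- Conj(e)
  c2 <- cos(theta)^2; s2 <- sin(theta)^2; cs <- cos(theta) * sin(theta)
  list(m11 = c2 * e + s2 * ec,
       m12 = cs * (e - ec),
       m22 = s2 * e + c2 * ec)   # m21 == m12 (symmetric linear retarder)
}

#' Cumulative round-trip sample Jones matrix at one depth
#'
#' Multiplies the one-way linear-retarder layer matrices of all planes from
#' the surface down to depth index `z` and closes the round trip by
#' reciprocity, `Js = t(P) P`. With `b = 0` everywhere this is the identity;
#' with a uniform axis the round-trip retardation accumulates as
#' `2 k0 b z_um`.
#'
#' @param phantom A [phantom_model()].
#' @param z Depth pixel index (1-based).
#' @return Complex array `(n_y, n_x, 2, 2)`.
#' @export
cumulative_sample_jones <- function(phantom, z) {
  g <- phantom$geometry
  if (z < 1L || z > g$n_z) stop("z out of range")
  ny <- g$n_y; nx <- g$n_x
  p11 <- matrix(1 + 0i, ny, nx); p12 <- matrix(0i, ny, nx)
  p21 <- matrix(0i, ny, nx); p22 <- matrix(1 + 0i, ny, nx)
  for (k in seq_len(z)) {
    L <- layer_components(matrix(phantom$b_map[k, , ], ny, nx),
                          matrix(phantom$theta_map[k, , ], ny, nx),
                          g$k0, g$depth_pitch)
    q11 <- L$m11 * p11 + L$m12 * p21
    q12 <- L$m11 * p12 + L$m12 * p22
    q21 <- L$m12 * p11 + L$m22 * p21
    q22 <- L$m12 * p12 + L$m22 * p22
    p11 <- q11; p12 <- q12; p21 <- q21; p22 <- q22
  }
  out <- array(0i, c(ny, nx, 2L, 2L))
  out[, , 1, 1] <- p11^2 + p21^2
  out[, , 1, 2] <- p11 * p12 + p21 * p22
  out[, , 2, 1] <- out[, , 1, 2]
  out[, , 2, 2] <- p12^2 + p22^2
  out
}

#' Simulate a JM-OCT volume from a phantom
#'
#' Per voxel the complex scatterer amplitude multiplies the cumulative
#' measured Jones matrix `Jout Js(z) Jin`; each en face plane of each channel
#' is then defocused by the forward Fresnel filter with `zd(z) = z -
#' focus_depth` (and, if `confocal`, the Gaussian beam envelope); finally
#' circular complex Gaussian noise is added to every channel. Identical seeds
#' give bit-identical volumes.
#'
#' @param phantom A [phantom_model()].
#' @param seed Scatterer RNG seed; defaults to the phantom's.
#' @param noise_seed RNG seed for the additive noise draw (kept separate so
#'   that repeated acquisitions of the same sample share scatterers but not
#'   noise).
#' @param pad_width Padding used when applying the forward defocus.
#' @return A [jones_volume()] with `noise_floor` set and a `ground_truth`
#'   list: `b_true`, `theta`, `zd_slope` (um/um), `zd_intercept` (um),
#'   `focus_depth`, `w0`, `noise_variance`, `seed`.
#' @export
simulate_jones_volume <- function(phantom, seed = phantom$seed,
                                  noise_seed = seed + 104729L,
                                  pad_width = 50L) {
  g <- phantom$geometry
  ny <- g$n_y; nx <- g$n_x; nz <- g$n_z
  set.seed(seed)
  n_vox <- nz * ny * nx
  occ <- stats::runif(n_vox) < phantom$scatterer_density
  amp <- complex(real = stats::rnorm(n_vox), imaginary = stats::rnorm(n_vox)) /
    sqrt(2) * phantom$amplitude_scale
  C <- array(occ * amp * phantom$amp_map, c(nz, ny, nx))

  env <- NULL
  if (phantom$confocal) {
    w0 <- beam_waist(g)
    fy <- dft_freqs(ny + 2L * pad_width, g$lateral_pitch_y)
    fx <- dft_freqs(nx + 2L * pad_width, g$lateral_pitch_x)
    env <- exp(-outer((pi * w0 * fy)^2, (pi * w0 * fx)^2, "+") / 2)
  }

  data <- array(0i, c(nz, ny, nx, 2L, 2L))
  p11 <- matrix(1 + 0i, ny, nx); p12 <- matrix(0i, ny, nx)
  p21 <- matrix(0i, ny, nx); p22 <- matrix(1 + 0i, ny, nx)
  Jin <- phantom$Jin; Jout <- phantom$Jout
  for (z in seq_len(nz)) {
    L <- layer_components(matrix(phantom$b_map[z, , ], ny, nx),
                          matrix(phantom$theta_map[z, , ], ny, nx),
                          g$k0, g$depth_pitch)
    q11 <- L$m11 * p11 + L$m12 * p21
    q12 <- L$m11 * p12 + L$m12 * p22
    q21 <- L$m12 * p11 + L$m22 * p21
    q22 <- L$m12 * p12 + L$m22 * p22
    p11 <- q11; p12 <- q12; p21 <- q21; p22 <- q22
    js11 <- p11^2 + p21^2
    js12 <- p11 * p12 + p21 * p22
    js22 <- p12^2 + p22^2
    # T = Js %*% Jin, Jm = Jout %*% T, elementwise over the plane
    t11 <- js11 * Jin[1, 1] + js12 * Jin[2, 1]
    t12 <- js11 * Jin[1, 2] + js12 * Jin[2, 2]
    t21 <- js12 * Jin[1, 1] + js22 * Jin[2, 1]
    t22 <- js12 * Jin[1, 2] + js22 * Jin[2, 2]
    cz <- matrix(C[z, , ], ny, nx)
    jm <- list(Jout[1, 1] * t11 + Jout[1, 2] * t21,
               Jout[1, 1] * t12 + Jout[1, 2] * t22,
               Jout[2, 1] * t11 + Jout[2, 2] * t21,
               Jout[2, 1] * t12 + Jout[2, 2] * t22)
    zd <- depth_um(g, z) - phantom$focus_depth
    ch <- 0L
    for (i in 1:2) for (j in 1:2) {
      ch <- ch + 1L
      f <- cz * jm[[ch]]
      if (zd != 0 || !is.null(env))
        f <- propagate_enface(f, g, zd, sign = +1, pad_width = pad_width,
                              amplitude_filter = env)
      data[z, , , i, j] <- f
    }
  }

  sigma2 <- phantom$noise_variance
  if (!is.null(phantom$snr_db)) {
    mean_I <- mean((Mod(data[, , , 1, 1])^2 + Mod(data[, , , 1, 2])^2 +
                    Mod(data[, , , 2, 1])^2 + Mod(data[, , , 2, 2])^2) / 4)
    sigma2 <- mean_I / 10^(phantom$snr_db / 10)
  }
  if (sigma2 > 0) {
    set.seed(noise_seed)
    n_all <- length(data)
    noise <- complex(real = stats::rnorm(n_all), imaginary = stats::rnorm(n_all)) *
      sqrt(sigma2 / 2)
    data <- data + array(noise, dim(data))
  }

  jones_volume(data, g, noise_floor = sigma2, ground_truth = list(
    b_true = phantom$b_map, theta = phantom$theta_map,
    zd_slope = 1, zd_intercept = -phantom$focus_depth,
    focus_depth = phantom$focus_depth,
    w0 = beam_waist(g), confocal = phantom$confocal,
    noise_variance = sigma2, seed = seed
  ))
}

#' Inject a known bulk phase error
#'
#' Multiplies every voxel of frame `y` (all four channels) by
#' `exp(i phases[y])`, emulating acquisition-time piston phase drift; the
#' injected sequence is stored in the ground truth for recovery tests.
#' Channel ratios at every voxel are unchanged (common factor).
#'
#' @param volume A [jones_volume()].
#' @param phases Numeric vector of length `n_y`, rad.
#' @return The corrupted [jones_volume()] (with `bulk_corrected = FALSE`).
#' @export
inject_bulk_phase_error <- function(volume, phases) {
  g <- volume$geometry
  if (length(phases) != g$n_y)
    stop("phases must have length n_y = ", g$n_y)
  d <- volume$data
  fac <- exp((0 + 1i) * phases)
  for (y in seq_len(g$n_y)) {
    if (phases[y] != 0) d[, y, , , ] <- d[, y, , , ] * fac[y]
  }
  gt <- volume$ground_truth
  if (is.null(gt)) gt <- list()
  gt$injected_phases <- phases
  jones_volume(d, g, bulk_corrected = FALSE, refocused = volume$refocused,
               noise_floor = volume$noise_floor, ground_truth = gt)
}

# smooth standardized 2-D Gaussian random field with (possibly anisotropic)
# correlation lengths in pixels (FFT filtering of white noise)
smooth_noise_2d <- function(ny, nx, corr_px, corr_px_x = corr_px) {
  w <- matrix(stats::rnorm(ny * nx), ny, nx)
  fy <- dft_freqs(ny, 1); fx <- dft_freqs(nx, 1)
  filt <- exp(-(outer((pi * corr_px * fy)^2, (pi * corr_px_x * fx)^2, "+")) / 2)
  sm <- Re(stats::fft(stats::fft(w + 0i) * filt, inverse = TRUE)) / (ny * nx)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Built-in phantom presets
#'
#' Three ready-made phantoms mirroring the validation samples a JM-OCT
#' refocusing study uses:
#' * `"foam"` - birefringent polygonal walls (b = 2.5e-3, two axis
#'   populations) embedded in a weakly birefringent scattering matrix;
#'   5.86 um lateral pitch. Dense speckle (density 1) with amplitude
#'   contrast between walls and matrix.
#' * `"muscle"` - oriented birefringent fibers (b = 2e-3 along the fast
#'   axis, a second weaker population at a tilted axis) in a low-b matrix;
#'   3.90625 um lateral pitch; dense speckle. The fiber field mixes two
#'   anisotropic correlation scales so fiber width/spacing are broadband
#'   like tissue rather than periodic.
#' * `"scattering"` - uniform non-birefringent particle suspension;
#'   2.93 um lateral pitch, confocal beam envelope enabled and a 7 um FWHM
#'   lateral resolution so that the depth-of-focus band sits inside the
#'   simulated depth span (for defocus-fit studies).
#'
#' @param name One of `"foam"`, `"muscle"`, `"scattering"`.
#' @param n_x,n_y,n_z Volume size in pixels.
#' @param focus_depth Focus depth in um; default mid-depth.
#' @param snr_db Target SNR in dB; `NULL` or `Inf` for noise-free.
#' @param seed RNG seed (structure masks and scatterers).
#' @return A [phantom_model()].
#' @export
phantom_preset <- function(name = c("foam", "muscle", "scattering"),
                           n_x = 256L, n_y = 256L, n_z = 64L,
                           focus_depth = NULL, snr_db = 25, seed = 1L) {
  name <- match.arg(name)
  if (!is.null(snr_db) && !is.finite(snr_db)) snr_db <- NULL
  if (name == "scattering") {
    g <- scan_geometry(n_x, n_y, n_z, lateral_pitch_x = 2.93,
                       lateral_resolution = 7)
    if (is.null(focus_depth)) focus_depth <- depth_um(g, n_z) / 2
    return(phantom_model(g, focus_depth, scatterer_density = 0.04,
                         snr_db = snr_db, confocal = TRUE, seed = seed))
  }
  if (name == "foam") {
    g <- scan_geometry(n_x, n_y, n_z, lateral_pitch_x = 5.86)
    if (is.null(focus_depth)) focus_depth <- depth_um(g, n_z) / 2
    set.seed(seed)
    s1 <- smooth_noise_2d(n_y, n_x, 14)
    s2 <- smooth_noise_2d(n_y, n_x, 20)
    wall2d <- abs(s1) < 0.25
    extrude <- function(m2d) aperm(array(m2d, c(n_y, n_x, n_z)), c(3, 1, 2))
    walls_a <- extrude(wall2d & s2 >= 0)
    walls_b <- extrude(wall2d & s2 < 0)
    regions <- list(
      list(mask = walls_a, theta = pi / 5, b = 2.5e-3, amplitude = 1.6),
      list(mask = walls_b, theta = -pi / 3, b = 2.5e-3, amplitude = 1.6)
    )
    return(phantom_model(g, focus_depth, scatterer_density = 1,
                         regions = regions, background_b = 2e-4,
                         snr_db = snr_db, confocal = FALSE, seed = seed))
  }
  # muscle
  g <- scan_geometry(n_x, n_y, n_z, lateral_pitch_x = 3.90625)
  if (is.null(focus_depth)) focus_depth <- depth_um(g, n_z) / 2
  set.seed(seed)
  # multi-scale anisotropic fiber field: long correlation along the fiber
  # axis (x), short across it, mixing two transverse scales so that fiber
  # width and spacing are broadband like real muscle rather than periodic
  s <- 0.6 * smooth_noise_2d(n_y, n_x, 5, 45) +
    0.4 * smooth_noise_2d(n_y, n_x, 14, 60)
  s <- s / stats::sd(s)
  fib1 <- s > 0.35
  fib2 <- s < -0.45
  extrude <- function(m2d) aperm(array(m2d, c(n_y, n_x, n_z)), c(3, 1, 2))
  regions <- list(
    list(mask = extrude(fib1), theta = 0, b = 2e-3, amplitude = 1.3),
    list(mask = extrude(fib2), theta = 0.6, b = 1.5e-3, amplitude = 1.15)
  )
  phantom_model(g, focus_depth, scatterer_density = 1, regions = regions,
                background_b = 3e-4, snr_db = snr_db, confocal = FALSE,
                seed = seed)
}
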