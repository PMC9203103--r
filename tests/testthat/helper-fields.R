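# Shared fixture builders. All fixtures are generated in code at test time.

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

circular_sd <- function(x) sqrt(-2 * log(Mod(mean(exp(1i * x)))))

# Band-limited sparse speckle: point scatterers in a centred support region,
# convolved with a Gaussian PSF of `sig_px` pixels. The Gaussian band limit
# makes defocused energy decay fast enough that zero-padding can contain it,
# which is what a real (aperture-limited) OCT field does too.
make_speckle_field <- function(seed, n = 128, density = 0.02, sig_px = 1.2,
                               pitch = 2.93, margin = round(n / 4)) {
  set.seed(seed)
  f0 <- matrix(0i, n, n)
  inner <- (margin + 1):(n - margin)
  m <- length(inner)^2
  f0[inner, inner] <- matrix(
    complex(real = rnorm(m), imaginary = rnorm(m)) * (runif(m) < density),
    length(inner))
  fr <- jmoct:::dft_freqs(n, pitch)
  env <- exp(-2 * pi^2 * (sig_px * pitch)^2 * outer(fr^2, fr^2, "+"))
  stats::fft(stats::fft(f0) * env, inverse = TRUE) / (n^2)
}

speckle_geometry <- function(n = 128, pitch = 2.93)
  scan_geometry(n, n, 4, lateral_pitch_x = pitch, lateral_resolution = 7)

# small uniform-retarder volume: dense speckle, uniform b and axis
uniform_retarder_volume <- function(b = 3e-3, theta = 0.4, n = 48, n_z = 16,
                                    focus_depth = 0, snr_db = NULL, seed = 3,
                                    pitch = 3.9) {
  g <- scan_geometry(n, n, n_z, lateral_pitch_x = pitch)
  ph <- phantom_model(g, focus_depth = focus_depth, scatterer_density = 1,
                      background_b = b, background_theta = theta,
                      snr_db = snr_db, seed = seed)
  simulate_jones_volume(ph)
}

# volume with a uniform polarization state (fixed Jones matrix times dense
# speckle) plus optional additive noise at a given SNR
uniform_state_volume <- function(J = jones_retarder(0.8, 0.5), n = 64,
                                 n_z = 3, snr_db = NULL, seed = 1) {
  g <- scan_geometry(n, n, n_z, lateral_pitch_x = 3.9)
  set.seed(seed)
  nv <- n_z * n * n
  amp <- array(complex(real = rnorm(nv), imaginary = rnorm(nv)) / sqrt(2),
               c(n_z, n, n))
  d <- array(0i, c(n_z, n, n, 2, 2))
  for (i in 1:2) for (j in 1:2) d[, , , i, j] <- amp * J[i, j]
  s2 <- 0
  if (!is.null(snr_db)) {
    s2 <- mean(Mod(d)^2) / 10^(snr_db / 10)
    d <- d + array(complex(real = rnorm(length(d)),
                           imaginary = rnorm(length(d))) * sqrt(s2 / 2), dim(d))
  }
  jones_volume(d, g, noise_floor = s2)
}

# mask of region-interior pixels: region membership eroded laterally by
# `erode` pixels, with an additional frame-edge margin (the frame edge
# truncates laterally blurred energy, so refocusing is not exact there)
interior_mask <- function(member, erode = 2, edge_margin = 16) {
  dims <- dim(member)
  er <- member
  for (s in seq_len(erode)) for (sg in c(-s, s)) {
    er <- er & member[, pmin(pmax(seq_len(dims[2]) + sg, 1), dims[2]), , drop = FALSE]
    er <- er & member[, , pmin(pmax(seq_len(dims[3]) + sg, 1), dims[3]), drop = FALSE]
  }
  if (edge_margin > 0) {
    er[, c(seq_len(edge_margin), (dims[2] - edge_margin + 1):dims[2]), ] <- FALSE
    er[, , c(seq_len(edge_margin), (dims[3] - edge_margin + 1):dims[3])] <- FALSE
  }
  er
}
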