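test_that("Stokes parameters follow from the detection-channel amplitudes", {
  g <- scan_geometry(2, 2, 1, lateral_pitch_x = 1)
  mk <- function(col) {
    d <- array(0i, c(1, 2, 2, 2, 2))
    d[1, , , 1, 1] <- col[1]; d[1, , , 2, 1] <- col[2]
    jones_volume(d, g)
  }
  s <- jones_to_stokes(mk(c(1, 0)))
  expect_equal(c(s$S0[1, 1, 1, 1], s$S1[1, 1, 1, 1],
                 s$S2[1, 1, 1, 1], s$S3[1, 1, 1, 1]), c(1, 1, 0, 0))
  s <- jones_to_stokes(mk(c(1, 1) / sqrt(2)))
  expect_equal(c(s$S0[1, 1, 1, 1], s$S1[1, 1, 1, 1],
                 s$S2[1, 1, 1, 1], s$S3[1, 1, 1, 1]), c(1, 0, 1, 0),
               tolerance = 1e-12)
  # random fully polarized states: S0^2 = S1^2 + S2^2 + S3^2
  set.seed(17)
  for (k in 1:20) {
    col <- complex(real = rnorm(2), imaginary = rnorm(2))
    s <- jones_to_stokes(mk(col))
    expect_equal(s$S0[1, 1, 1, 1]^2,
                 s$S1[1, 1, 1, 1]^2 + s$S2[1, 1, 1, 1]^2 + s$S3[1, 1, 1, 1]^2,
                 tolerance = 1e-12)
  }
})

test_that("DOPU is 1 for uniform fields and ~0 for alternating states", {
  vol <- uniform_state_volume()
  du <- compute_dopu(jones_to_stokes(vol))
  expect_equal(mean(du$dopu[, 2:63, 2:63]), 1, tolerance = 1e-12)
  expect_true(all(du$dopu >= 0 & du$dopu <= 1, na.rm = TRUE))

  # checkerboard of orthogonal states with equal intensity: averaged Stokes
  # vector cancels inside any 3x3 kernel
  g <- scan_geometry(16, 16, 1, lateral_pitch_x = 1)
  d <- array(0i, c(1, 16, 16, 2, 2))
  chk <- outer(1:16, 1:16, function(a, b) (a + b) %% 2 == 0)
  d[1, , , 1, 1][chk] <- 1; d[1, , , 2, 1][!chk] <- 1
  d[1, , , 1, 2][chk] <- 1; d[1, , , 2, 2][!chk] <- 1
  du0 <- compute_dopu(jones_to_stokes(jones_volume(d, g)))
  expect_lt(max(du0$dopu[1, 2:15, 2:15]), 0.15)
})

test_that("noise-corrected DOPU beats the uncorrected estimate at every SNR", {
  for (snr in c(10, 15, 20, 25)) {
    vol <- uniform_state_volume(snr_db = snr, seed = snr)
    st <- jones_to_stokes(vol)
    d_c <- mean(compute_dopu(st, corrected = TRUE)$dopu, na.rm = TRUE)
    d_u <- mean(compute_dopu(st, corrected = FALSE)$dopu, na.rm = TRUE)
    expect_gte(d_c, d_u)
    expect_lt(abs(d_c - 1), abs(d_u - 1))
    if (snr == 20) expect_lt(abs(d_c - 1), 0.02)
  }
})

test_that("DOPU decreases under increasing polarization scrambling", {
  # polarization axis scrambled with growing spatial randomness
  g <- scan_geometry(48, 48, 1, lateral_pitch_x = 1)
  dopu_at <- function(scramble) {
    set.seed(99)
    theta <- matrix(rnorm(48 * 48, 0, scramble), 48)
    d <- array(0i, c(1, 48, 48, 2, 2))
    for (y in 1:48) for (x in 1:48) {
      J <- jones_retarder(1.2, theta[y, x])
      d[1, y, x, , ] <- J
    }
    mean(compute_dopu(jones_to_stokes(jones_volume(d, g)))$dopu, na.rm = TRUE)
  }
  vals <- vapply(c(0, 0.2, 0.5, 1), dopu_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("kernel larger than the field is rejected", {
  vol <- uniform_state_volume(n = 4)
  expect_error(compute_dopu(jones_to_stokes(vol), kernel = c(9, 9)), "kernel")
})

test_that("pseudo-colour birefringence encodes hue/saturation/value as documented", {
  set.seed(2)
  b <- matrix(runif(64, 0, 8e-3), 8)
  I <- matrix(rexp(64) + 0.1, 8)
  rel <- matrix(runif(64), 8)
  img <- pseudo_color_birefringence(b, I, rel)
  expect_equal(dim(img$rgb), c(8, 8, 3))
  # reliability 0 -> grayscale
  gray <- pseudo_color_birefringence(b, I, matrix(0, 8, 8))
  expect_equal(gray$rgb[, , 1], gray$rgb[, , 2])
  expect_equal(gray$rgb[, , 2], gray$rgb[, , 3])
  # constant b, constant reliability -> constant hue
  cimg <- pseudo_color_birefringence(matrix(4e-3, 8, 8), I, matrix(1, 8, 8))
  hsvs <- grDevices::rgb2hsv(t(matrix(cimg$rgb, 64, 3)))
  expect_lt(diff(range(hsvs["h", ])), 1e-6)
  # hue decodes back to b within 8-bit quantization of the hue range
  q <- round(img$rgb * 255) / 255
  hq <- grDevices::rgb2hsv(t(matrix(q, 64, 3)))["h", ]
  b_back <- hq / (2 / 3) * 8e-3
  bright <- as.numeric(img$rgb[, , 1] + img$rgb[, , 2] + img$rgb[, , 3]) > 0.2
  expect_lt(max(abs(b_back - as.numeric(b))[bright & as.numeric(rel) > 0.2]),
            8e-3 / 100)
  expect_error(pseudo_color_birefringence(b, I[1:4, ], rel), "shapes")
})

test_that("pseudo-colour DOPU renders low intensity gray and ramps hue monotonically", {
  n <- 16
  dopu <- matrix(seq(0, 1, length.out = n * n), n)
  I <- matrix(1000, n, n)
  img <- pseudo_color_dopu(dopu, I, db_window = c(0, 40))
  # fixed intensity, monotone dopu -> monotone hue from yellow (1/6) to red (0)
  hs <- grDevices::rgb2hsv(t(matrix(img$rgb, n * n, 3)))["h", ]
  expect_true(all(diff(hs) <= 1e-9))
  # floor intensity -> gray regardless of dopu
  img2 <- pseudo_color_dopu(dopu, matrix(1e-30, n, n), db_window = c(0, 40))
  expect_lt(max(abs(img2$rgb[, , 1] - img2$rgb[, , 2])), 1e-9)
  # high dopu at high intensity is in the red family
  red <- pseudo_color_dopu(matrix(1, 2, 2), matrix(1e4, 2, 2),
                           db_window = c(0, 40))
  expect_gt(red$rgb[1, 1, 1], red$rgb[1, 1, 2])
  expect_gt(red$rgb[1, 1, 1], red$rgb[1, 1, 3])
  expect_error(pseudo_color_dopu(dopu, I[1:4, ]), "shapes")
})
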