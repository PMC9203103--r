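test_that("Fresnel filter matches the quadratic-phase formula", {
  g <- speckle_geometry(64, pitch = 1)
  H0 <- fresnel_filter(c(16, 16), g, 0, sign = -1)
  expect_equal(H0, matrix(1 + 0i, 16, 16))
  # hand value: lambda 1.31, zd 100, fx = 0.1, fy = 0 -> phase -4.115 rad
  H <- fresnel_filter(c(10, 10), g, 100, sign = -1)
  fx <- jmoct:::dft_freqs(10, 1)
  ix <- which(abs(fx - 0.1) < 1e-12)
  want <- -pi * 1.31 * 100 * 0.01
  expect_equal(Arg(H[1, ix]), want + 2 * pi, tolerance = 1e-10)
  # phase-only for random zd; refocus is the conjugate of defocus
  set.seed(3)
  for (zd in runif(3, -900, 900)) {
    Hm <- fresnel_filter(c(12, 20), g, zd, sign = -1)
    Hp <- fresnel_filter(c(12, 20), g, zd, sign = +1)
    expect_equal(max(abs(Mod(Hm) - 1)), 0, tolerance = 1e-12)
    expect_equal(Hm, Conj(Hp))
  }
  expect_error(fresnel_filter(c(4, 4), g, NaN), "finite")
})

test_that("propagation is the identity at zero defocus and inverts exactly", {
  g <- speckle_geometry(128)
  f <- make_speckle_field(11, sig_px = 3)
  expect_equal(propagate_enface(f, g, 0), f + 0i)
  fd <- propagate_enface(f, g, 300, sign = +1)
  expect_lt(rel_l2(propagate_enface(fd, g, 300, sign = -1), f), 1e-10)
  # phase-only filtering conserves energy when the support stays inside
  expect_lt(abs(sum(Mod(fd)^2) / sum(Mod(f)^2) - 1), 1e-10)
  expect_error(propagate_enface(f, g, 10, pad_width = -1), "pad_width")
})

test_that("image entropy matches hand-computed values", {
  expect_equal(image_entropy(c(0, 5, 0, 0)), 0)
  expect_equal(image_entropy(rep(2, 4)), log(4))
  expect_equal(image_entropy(c(1, 1, 2, 0)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_error(image_entropy(c(0, 0)), "zero")
  expect_error(image_entropy(c(-1, 2)), "nonnegative")
})

test_that("entropy minimization recovers the defocus of a single plane", {
  g <- speckle_geometry(128)
  f <- make_speckle_field(21)
  # in-focus field: |zd| well below DOF/20
  est0 <- estimate_defocus_plane(f, g)
  expect_lt(abs(est0$zd), dof_halfwidth(g) / 20)
  # computationally defocused by 300 um: recovered within 10 um
  fd <- propagate_enface(f, g, 300, sign = +1)
  est <- estimate_defocus_plane(fd, g)
  expect_lt(abs(est$zd - 300), 10)
  # the optimum is at least as sharp as not refocusing at all
  expect_lte(est$entropy, image_entropy(Mod(fd)^2) + 1e-12)
})

test_that("defocus estimates are consistent across seeds and defocus", {
  g <- speckle_geometry(128)
  errs <- c()
  for (seed in 1:10) {
    zd_true <- c(-600, -300, -100, 100, 300, 600)[(seed - 1) %% 6 + 1]
    f <- make_speckle_field(seed + 100)
    fd <- propagate_enface(f, g, zd_true, sign = +1)
    s2 <- mean(Mod(fd)^2) / 100                      # 20 dB SNR
    set.seed(seed)
    noise <- matrix(complex(real = rnorm(128^2), imaginary = rnorm(128^2)) *
                      sqrt(s2 / 2), 128)
    est <- estimate_defocus_plane(fd + noise, g)
    errs <- c(errs, abs(est$zd - zd_true))
  }
  expect_lt(median(errs), 10)
})

test_that("per-depth estimation flags low-signal blocks and errors when none", {
  ph <- phantom_preset("scattering", n_x = 64, n_y = 64, n_z = 16,
                       snr_db = 25, seed = 8, focus_depth = 300)
  vol <- simulate_jones_volume(ph)
  # empty the bottom half: those blocks fall below the signal margin
  d <- vol$data
  d[9:16, , , , ] <- 0i
  dark <- jones_volume(d, vol$geometry, noise_floor = vol$noise_floor)
  prof <- estimate_defocus_profile(dark, block = 4)
  expect_false(any(prof$valid[3:4]))
  expect_true(any(prof$valid[1:2]))
  all_dark <- jones_volume(array(0i, dim(d)), vol$geometry,
                           noise_floor = vol$noise_floor)
  expect_error(estimate_defocus_profile(all_dark, block = 4), "signal margin")
})

test_that("linear defocus fit recovers exact lines and respects the DOF band", {
  mkprof <- function(z, zd, valid = rep(TRUE, length(z))) {
    structure(list(depth_index = seq_along(z), depth_um = z, zd_um = zd,
                   entropy = rep(0, length(z)), valid = valid,
                   slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, dof_halfwidth = NA_real_,
                   used = NULL, residuals = NULL),
              class = "defocus_profile")
  }
  z <- seq(0, 900, by = 60)
  prof <- fit_defocus_linear(mkprof(z, 0.97 * z - 410), dof_halfwidth = 80)
  expect_equal(prof$slope, 0.97, tolerance = 1e-9)
  expect_equal(prof$intercept, -410, tolerance = 1e-6)
  expect_equal(prof$r_squared, 1, tolerance = 1e-12)
  # points predicted inside the DOF band are excluded even when valid
  expect_false(any(prof$used[abs(0.97 * z - 410) < 80]))
  expect_true(all(prof$used[abs(0.97 * z - 410) > 120]))

  # jittered line: slope recovered within 3 standard errors (lm oracle)
  set.seed(5)
  zj <- seq(0, 950, by = 50)
  zdj <- 1.02 * zj - 500 + rnorm(20, 0, 5)
  fitj <- fit_defocus_linear(mkprof(zj, zdj), dof_halfwidth = 0)
  oracle <- stats::lm(zdj ~ zj)
  se <- summary(oracle)$coefficients["zj", "Std. Error"]
  expect_equal(fitj$slope, unname(coef(oracle)[2]), tolerance = 1e-9)
  expect_lt(abs(fitj$slope - 1.02), 3 * se)
  expect_error(fit_defocus_linear(mkprof(c(0, 60), c(1, 2), valid = c(TRUE, FALSE)),
                                  dof_halfwidth = 10), "at least 2")
})

test_that("bulk phase correction removes injected piston phases", {
  ph <- phantom_preset("scattering", n_x = 96, n_y = 96, n_z = 16,
                       snr_db = 25, seed = 12, focus_depth = 400)
  vol <- simulate_jones_volume(ph)
  set.seed(30)
  phases <- cumsum(rnorm(96, 0, 0.5))
  bad <- inject_bulk_phase_error(vol, phases)
  fixed <- bulk_phase_correct(bad)
  expect_true(fixed$bulk_corrected)
  # recovered piston tracks the injected sequence: the circular variance of
  # the residual increments is >= 10x smaller than that of the injected walk
  resid <- fixed$bulk_phase_estimate - phases
  cvar <- function(x) 1 - Mod(mean(exp(1i * x)))
  expect_gt(cvar(diff(phases)) / cvar(diff(resid)), 10)
  # identical correction on all channels: channel ratios unchanged
  i0 <- which(Mod(bad$data[8, 48, , 1, 1]) > 0)[1]
  r_before <- bad$data[8, 48, i0, 2, 2] / bad$data[8, 48, i0, 1, 1]
  r_after <- fixed$data[8, 48, i0, 2, 2] / fixed$data[8, 48, i0, 1, 1]
  expect_equal(r_after, r_before, tolerance = 1e-12)
})

test_that("bulk correction on a clean volume is nearly inert away from the frame edge", {
  ph <- phantom_preset("scattering", n_x = 192, n_y = 192, n_z = 32,
                       snr_db = 25, seed = 4, focus_depth = 500)
  vol <- simulate_jones_volume(ph)
  corr <- bulk_phase_correct(vol)
  inc <- diff(corr$bulk_phase_estimate)
  # interior frames only: the frame edge carries a systematic truncated-chirp
  # phase that is a finite-field artifact, not acquisition phase noise
  expect_lt(circular_sd(inc[30:160]), 0.05)
})

test_that("volume refocusing undoes simulated defocus and lowers entropy", {
  ph <- phantom_preset("scattering", n_x = 96, n_y = 96, n_z = 12,
                       snr_db = NULL, seed = 6, focus_depth = 400)
  vol <- simulate_jones_volume(ph)
  gt <- vol$ground_truth
  prof <- manual_defocus_profile(gt$zd_slope, gt$zd_intercept)
  ref <- refocus_volume(vol, prof)
  expect_true(ref$refocused)
  for (z in c(2, 6, 11)) {
    e0 <- image_entropy(Mod(enface_field(vol, z))^2)
    e1 <- image_entropy(Mod(enface_field(ref, z))^2)
    expect_lte(e1, e0 + 1e-9)
  }
  # a zero line leaves the volume untouched
  same <- refocus_volume(vol, manual_defocus_profile(0, 0))
  expect_equal(same$data, vol$data)
  expect_error(refocus_volume(vol, list(slope = 1)), "defocus_profile")
})
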