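# helper: build a tiny volume with prescribed Jones matrices at two depths,
# constant across the lateral field
two_plane_volume <- function(J1, J2, ny = 3, nx = 3) {
  g <- scan_geometry(nx, ny, 2, lateral_pitch_x = 3.9)
  d <- array(0i, c(2, ny, nx, 2, 2))
  for (i in 1:2) for (j in 1:2) {
    d[1, , , i, j] <- J1[i, j]
    d[2, , , i, j] <- J2[i, j]
  }
  jones_volume(d, g)
}

test_that("local Jones matrix is Jm(z2) Jm(z1)^-1", {
  I2 <- diag(2) + 0i
  D <- diag(exp(c(1i, -1i) * pi / 8))
  # identity in, identity out
  loc <- cumulative_to_local(two_plane_volume(I2, I2), 1, 2)
  expect_equal(loc$data[1, 1, , ], I2, tolerance = 1e-14)
  # identity at z1 passes J2 through
  loc <- cumulative_to_local(two_plane_volume(I2, D), 1, 2)
  expect_equal(loc$data[2, 2, , ], D, tolerance = 1e-14)
  expect_equal(loc$Zd, 7.24)

  # random invertible pairs against an independent solve() oracle
  set.seed(41)
  for (k in 1:25) {
    J1 <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2)
    J2 <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2)
    loc <- cumulative_to_local(two_plane_volume(J1, J2), 1, 2)
    expect_equal(loc$data[1, 1, , ], J2 %*% solve(J1), tolerance = 1e-10)
  }
})

test_that("local Jones guards depth ordering and singular planes", {
  I2 <- diag(2) + 0i
  vol <- two_plane_volume(I2, I2)
  expect_error(cumulative_to_local(vol, 2, 1), "greater")
  expect_error(cumulative_to_local(vol, 1, 3), "range")
  z0 <- two_plane_volume(matrix(0i, 2, 2), I2)
  expect_warning(loc <- cumulative_to_local(z0, 1, 2), "singular")
  expect_false(any(loc$valid))
})

test_that("phase retardation is the wrapped eigenvalue phase difference", {
  I2 <- diag(2) + 0i
  D <- diag(exp(c(1i, -1i) * pi / 8))
  ret <- phase_retardation(cumulative_to_local(two_plane_volume(I2, I2), 1, 2))
  expect_equal(max(abs(ret$delta)), 0)
  ret <- phase_retardation(cumulative_to_local(two_plane_volume(I2, D), 1, 2))
  expect_equal(ret$delta[2, 2], pi / 4, tolerance = 1e-12)
})

test_that("phase retardation is similarity invariant", {
  set.seed(7)
  D <- diag(exp(c(1i, -1i) * pi / 8))
  for (k in 1:100) {
    A <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2)
    J <- A %*% D %*% solve(A)
    ret <- phase_retardation(cumulative_to_local(
      two_plane_volume(diag(2) + 0i, J), 1, 2))
    expect_equal(ret$delta[1, 1], pi / 4, tolerance = 1e-9)
  }
})

test_that("retardation converts to birefringence by delta / (2 k0 Zd)", {
  I2 <- diag(2) + 0i
  D <- diag(exp(c(1i, -1i) * pi / 8))
  ret <- phase_retardation(cumulative_to_local(two_plane_volume(I2, D), 1, 2))
  k0 <- 2 * pi / 1.31
  bm <- retardation_to_birefringence(ret, Zd = 57.9, k0 = k0)
  expect_equal(bm$b[1, 1], (pi / 4) / (2 * k0 * 57.9), tolerance = 1e-12)
  # delta = pi over the standard 8-pixel window: b ~ 5.66e-3
  r_pi <- ret; r_pi$delta[] <- pi
  b_pi <- retardation_to_birefringence(r_pi, Zd = 57.9, k0 = k0)
  expect_equal(b_pi$b[1, 1], 5.66e-3, tolerance = 1e-3)
  # doubling Zd halves b
  half <- retardation_to_birefringence(ret, Zd = 2 * 57.9, k0 = k0)
  expect_equal(half$b, bm$b / 2, tolerance = 1e-14)
  expect_error(retardation_to_birefringence(ret, Zd = 0, k0 = k0), "Zd")
})

test_that("retardation and birefringence respect their ranges", {
  set.seed(13)
  g <- scan_geometry(6, 6, 10, lateral_pitch_x = 3.9)
  d <- array(complex(real = rnorm(10 * 6 * 6 * 4),
                     imaginary = rnorm(10 * 6 * 6 * 4)), c(10, 6, 6, 2, 2))
  vol <- jones_volume(d, g)
  bm <- birefringence_map(vol, Zd_pixels = 4)
  k0 <- g$k0; Zd <- 4 * g$depth_pitch
  expect_true(all(bm$b >= 0 & bm$b <= pi / (2 * k0 * Zd) + 1e-12))
  expect_true(all(bm$reliability >= 0 & bm$reliability <= 1))
  expect_equal(bm$Zd, Zd)
})

test_that("retardation chain is consistent for aligned unitary layers", {
  # three planes of a uniform-axis retarder: delta(1,3) = delta(1,2) + delta(2,3)
  g <- scan_geometry(2, 2, 3, lateral_pitch_x = 3.9)
  step <- function(phi) diag(exp(c(1i, -1i) * phi / 2))
  d <- array(0i, c(3, 2, 2, 2, 2))
  cum <- diag(2) + 0i
  phis <- c(0, 0.5, 0.8)
  for (z in 1:3) {
    cum <- step(phis[z]) %*% cum
    Js <- t(cum) %*% cum
    for (i in 1:2) for (j in 1:2) d[z, , , i, j] <- Js[i, j]
  }
  vol <- jones_volume(d, g)
  d12 <- phase_retardation(cumulative_to_local(vol, 1, 2))$delta[1, 1]
  d23 <- phase_retardation(cumulative_to_local(vol, 2, 3))$delta[1, 1]
  d13 <- phase_retardation(cumulative_to_local(vol, 1, 3))$delta[1, 1]
  expect_equal(d13, d12 + d23, tolerance = 1e-10)
})

test_that("uniform retarder birefringence is recovered within 5%", {
  vol <- uniform_retarder_volume(b = 3e-3, n = 32, n_z = 16)
  bm <- birefringence_map(vol, Zd_pixels = 8)
  expect_lt(max(abs(bm$b - 3e-3) / 3e-3), 0.05)
})

test_that("composite intensity averages the four channel intensities", {
  g <- scan_geometry(2, 2, 1, lateral_pitch_x = 1)
  d <- array(0i, c(1, 2, 2, 2, 2))
  d[1, , , , ] <- exp(1i * 0.3)              # all four channels modulus 1
  vol <- jones_volume(d, g)
  expect_equal(as.numeric(intensity_composite(vol)), rep(1, 4))
  d2 <- array(0i, c(1, 2, 2, 2, 2)); d2[1, , , 1, 1] <- 2
  expect_equal(as.numeric(intensity_composite(jones_volume(d2, g))), rep(1, 4))
  set.seed(5)
  d3 <- array(complex(real = rnorm(16), imaginary = rnorm(16)), c(1, 2, 2, 2, 2))
  want <- apply(Mod(d3)^2, c(1, 2, 3), mean)
  expect_equal(intensity_composite(jones_volume(d3, g)), want, tolerance = 1e-14)
})
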