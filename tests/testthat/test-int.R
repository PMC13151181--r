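test_that("biased ACF matches the double-loop oracle", {
  acf_oracle <- function(x, L) {
    T <- length(x); d <- x - mean(x)
    den <- sum(d * d)
    vapply(0:L, function(k) {
      s <- 0
      for (t in seq_len(T - k)) s <- s + d[t] * d[t + k]
      s / den
    }, numeric(1))
  }
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(60)
    a <- acf_biased(x, max_lag = 12)
    expect_lt(max(abs(a$rho - acf_oracle(x, 12))), 1e-10)
    expect_equal(a$rho[1], 1)
  }
  # alternating series: rho[1] = -(T-1)/T
  alt <- rep(c(1, -1), 50)
  expect_equal(acf_biased(alt, 2)$rho[2], -99 / 100, tolerance = 1e-12)
  expect_error(acf_biased(rep(3, 50)), "constant")
})

test_that("ACF estimates approach population values", {
  set.seed(22)
  # white noise: lag-1 near zero
  expect_lt(abs(acf_biased(rnorm(1e4), 1)$rho[2]), 0.05)
  # AR(1) phi = 0.5 at T = 1e5: rho[1] within 0.01
  x <- ar1_series(1e5, 0.5)
  expect_lt(abs(acf_biased(x, 1)$rho[2] - 0.5), 0.01)
})

test_that("positive-area walk implements the stopping rule", {
  r <- c(1, 0.5, 0.2, -0.1, 0.3)
  out <- int_from_acf(r, tr = 2, include_lag0 = TRUE)
  expect_equal(out$seconds, 3.4)       # the later 0.3 is never reached
  expect_equal(out$n_positive_lags, 3)
  r2 <- c(1, -0.3, 0.5)
  expect_equal(int_from_acf(r2, 2, include_lag0 = TRUE)$seconds, 2.0)
  expect_equal(int_from_acf(r2, 2, include_lag0 = FALSE)$seconds, 0.0)
})

test_that("timescale recovers the AR(1) geometric sum at large T", {
  # analytic value: TR * (1 + phi / (1 - phi)). Short runs truncate the
  # positive run of the empirical ACF and shorten the estimate; long
  # runs land within a few percent of the closed form (the stopping
  # rule leaves a small positive remainder that decays only slowly, so
  # exact unbiasedness is not expected at any finite T).
  phi <- 0.6; tr <- 2
  truth <- tr * (1 + phi / (1 - phi))   # 5.0 s
  set.seed(23)
  mean_int <- function(T, nv) {
    mean(vapply(seq_len(nv), function(i) {
      int_from_acf(acf_biased(ar1_series(T, phi), max_lag = 200), tr)$seconds
    }, numeric(1)))
  }
  m_long <- mean_int(10000, 40)
  expect_lt(abs(m_long - truth) / truth, 0.05)
  m_short <- mean_int(100, 300)
  expect_lt(m_short, truth)             # truncation shortens short runs
  expect_lt(m_short, m_long)
})

test_that("voxel-wise map is deterministic, masked, and scale-invariant", {
  set.seed(24)
  Y <- matrix(rnorm(190 * 27), 190, 27)
  fx <- bold_from_matrix(Y, c(3, 3, 3))
  m1 <- compute_int_map(fx$bold, fx$mask)
  m2 <- compute_int_map(fx$bold, fx$mask)
  expect_identical(m1$data, m2$data)
  # affine rescale of the series changes nothing
  fx2 <- bold_from_matrix(3.7 * Y + 11, c(3, 3, 3))
  expect_equal(compute_int_map(fx2$bold, fx$mask)$data, m1$data,
               tolerance = 1e-10)
  # single-voxel mask -> exactly one finite value
  mk <- array(FALSE, c(3, 3, 3)); mk[2, 2, 2] <- TRUE
  m3 <- compute_int_map(fx$bold, brain_mask(fx$bold$grid, mk))
  expect_equal(sum(is.finite(m3$data)), 1)
})

test_that("timescale is monotone in phi and near TR for white noise", {
  set.seed(25)
  T <- 190; nv <- 200; tr <- 2
  phis <- seq(0.1, 0.8, by = 0.1)
  means <- vapply(phis, function(phi) {
    Y <- matrix(0, T, nv)
    x <- rnorm(nv)
    s <- sqrt(1 - phi^2)
    Y[1, ] <- x
    for (t in 2:T) { x <- phi * x + s * rnorm(nv); Y[t, ] <- x }
    fx <- bold_from_matrix(Y, c(5, 5, 8))
    mean(compute_int_map(fx$bold, fx$mask)$data)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # white noise: mean timescale within 10% of TR (lag 0 included)
  Y0 <- matrix(rnorm(T * nv), T, nv)
  fx0 <- bold_from_matrix(Y0, c(5, 5, 8))
  expect_lt(abs(mean(compute_int_map(fx0$bold, fx0$mask)$data) - tr),
            0.1 * tr)
})

test_that("mask-aware smoothing conserves constants and kernel shape", {
  grid <- centered_grid(c(21, 21, 21), 3)
  mask <- brain_mask(grid, array(TRUE, c(21, 21, 21)))
  set.seed(26)
  m <- voxel_map(grid, array(rnorm(21^3), c(21, 21, 21)))
  expect_identical(smooth_map(m, 0, mask)$data, m$data)  # fwhm 0 identity
  const <- voxel_map(grid, array(4.2, c(21, 21, 21)))
  sc <- smooth_map(const, 6, mask)
  expect_equal(sc$data[mask$data], rep(4.2, 21^3), tolerance = 1e-10)
  # delta far from the edge reproduces the separable Gaussian profile
  dl <- array(0, c(21, 21, 21)); dl[11, 11, 11] <- 1
  sm <- smooth_map(voxel_map(grid, dl), 6, mask)
  sig <- 6 / (3 * 2 * sqrt(2 * log(2)))
  w <- function(d) dnorm(d, sd = sig) / sum(dnorm(-10:10, sd = sig))
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(1, 1, 1))) {
    expected <- prod(vapply(off, w, numeric(1)))
    expect_equal(sm$data[11 + off[1], 11 + off[2], 11 + off[3]],
                 expected, tolerance = 1e-3)
  }
})

test_that("smoothing does not bleed signal across the mask edge", {
  grid <- centered_grid(c(15, 15, 15), 3)
  mk <- array(FALSE, c(15, 15, 15)); mk[4:12, 4:12, 4:12] <- TRUE
  mask <- brain_mask(grid, mk)
  m <- voxel_map(grid, array(1, c(15, 15, 15)))
  out <- smooth_map(m, 8, mask)
  expect_true(all(is.finite(out$data[mk])))
  expect_equal(out$data[mk], rep(1, sum(mk)), tolerance = 1e-10)
  expect_true(all(is.nan(out$data[!mk])))
})

test_that("z-transform standardizes, preserves ranks, ignores scale", {
  grid <- centered_grid(c(9, 9, 9), 3)
  mk <- array(TRUE, c(9, 9, 9))
  mask <- brain_mask(grid, mk)
  set.seed(27)
  m <- voxel_map(grid, array(rnorm(9^3, 5, 2), c(9, 9, 9)))
  z <- zscore_map(m, mask)
  v <- z$data[mk]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sd(v) - 1), 1e-10)
  m2 <- voxel_map(grid, 3 * m$data + 7)
  expect_equal(zscore_map(m2, mask)$data, z$data, tolerance = 1e-10)
  expect_identical(order(v), order(m$data[mk]))
  expect_error(zscore_map(voxel_map(grid, array(1, c(9, 9, 9))), mask),
               "variance")
})
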