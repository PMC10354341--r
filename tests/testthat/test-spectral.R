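test_that("Welch estimate satisfies Parseval for white noise", {
  set.seed(11)
  x <- signal_trace(rnorm(30000), 1000)
  psd <- welch_psd(x)
  expect_equal(psd$frequencies, 0:500)
  expect_equal(sum(psd$values), 1, tolerance = 0.05)
  expect_error(welch_psd(signal_trace(rnorm(500), 1000)), "too short")
})

test_that("a pure sinusoid concentrates its power at its bin", {
  A <- 0.3
  x <- signal_trace(A * sin(2 * pi * 10 * (0:29999) / 1000), 1000)
  psd <- welch_psd(x)
  near <- psd$frequencies >= 9 & psd$frequencies <= 11
  expect_equal(sum(psd$values[near]), A^2 / 2, tolerance = 0.01)
  expect_lt(sum(psd$values[!near]), 0.01 * A^2 / 2)   # leakage below 1%
})

test_that("band activity sums inclusive 1 Hz bins", {
  flat <- psd_series(0:500, rep(1, 501))
  expect_equal(band_activity(flat, c(8, 12)), 5)
  expect_equal(band_activity(flat, c(25, 55)), 31)
  zero <- psd_series(0:500, rep(0, 501))
  expect_equal(band_activity(zero, c(8, 12)), 0)
  expect_error(band_activity(flat, c(1000, 2000)), "no PSD bins")
})

test_that("amplitude ratio identities hold", {
  p <- psd_series(0:100, abs(rnorm(101)) + 0.1)
  expect_equal(amplitude_ratio(p, p), 1)
  p4 <- psd_series(0:100, 4 * p$values)
  expect_equal(amplitude_ratio(p4, p), 2)                    # sqrt convention
  expect_equal(amplitude_ratio(p4, p, type = "power"), 4)
  expect_error(amplitude_ratio(p, psd_series(0:100, rep(0, 101))), "zero")
})

test_that("gain extraction recovers a known plant response", {
  # equal spectra: no response at all
  p <- psd_series(0:100, abs(rnorm(101)) + 0.1)
  u <- psd_series(0:100, rep(1, 101))
  g0 <- extract_gain(p, p, u, f_range = c(1, 100))
  expect_equal(g0$magnitude_squared, rep(0, 100))

  # synthetic y = g * u + y0 with a known 2-pole g and white input
  set.seed(21)
  dt <- 1e-3
  g <- transfer_function(c(30, 0), c(1, 30, (2 * pi * 15)^2))
  gd <- discretize(to_state_space(g), dt)
  n <- 30000
  un <- rnorm(n, sd = 0.1)
  y0n <- rnorm(n, sd = 0.02)
  resp <- simulate_lti(gd, matrix(un, ncol = 1))$samples
  Py <- welch_psd(signal_trace(resp + y0n, 1000))
  Py0 <- welch_psd(signal_trace(rnorm(n, sd = 0.02), 1000))
  Pu <- welch_psd(signal_trace(un, 1000))
  gs <- extract_gain(Py, Py0, Pu)
  truth <- Mod(frequency_response(gd, gs$frequencies))^2
  # within 3 standard errors per bin, allowing the chi-squared spread
  n_eff <- Py$n_segments / 2
  se <- 3 * sqrt(Py$values[-1]^2 + Py0$values[-1]^2)[1:100] / sqrt(n_eff) /
    Pu$values[2:101]
  expect_true(mean(abs(gs$magnitude_squared - truth) <= se) > 0.95)

  # flooring rule: negative differences are clipped and counted
  lo <- psd_series(0:100, rep(0.5, 101))
  hi <- psd_series(0:100, rep(1, 101))
  gneg <- extract_gain(lo, hi, u, f_range = c(1, 100))
  expect_equal(gneg$magnitude_squared, rep(0, 100))
  expect_equal(gneg$n_floored, 100L)
})

test_that("gain extraction is invariant to input rescaling", {
  tr <- estimation_trial(31)
  # scaling u by c scales S_uu and S_yy - S_y0y0 by c^2: redo with doubled u
  pars <- linear_brain_params()
  u <- white_noise_input(30, sd = 0.005, seed = 31 * 1000 + 1)
  u2 <- signal_trace(2 * u$samples, u$sampling_rate)
  y0 <- simulate_linear_brain(pars, 30, seed = 31 * 1000 + 100)
  y2 <- simulate_linear_brain(pars, 30, input = u2, seed = 31 * 1000 + 200)
  gs2 <- extract_gain(welch_psd(y2), welch_psd(y0), welch_psd(u2))
  # same realization, quadrupled input power: recovered |g|^2 agrees up to
  # estimator noise (compare medians of the ratio where both are positive)
  ok <- tr$gain$magnitude_squared > 0 & gs2$magnitude_squared > 0
  ratio <- gs2$magnitude_squared[ok] / tr$gain$magnitude_squared[ok]
  expect_equal(median(ratio), 1, tolerance = 0.25)
})

test_that("mean spectral amplitude uses the amplitude spectrum", {
  p <- psd_series(0:3, c(4, 9, 16, 25))
  expect_equal(mean_amplitude(p), 2 + 3 + 4 + 5)
})
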