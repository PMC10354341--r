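test_that("exact magnitude data is fitted to numerical precision", {
  # first-order low-pass sampled on a log grid
  G1 <- transfer_function(1, c(1 / (2 * pi * 10), 1))
  f <- probe_grid(200, 0.1, 100)
  d1 <- gain_samples(f, Mod(frequency_response(G1, f))^2)
  fit1 <- magnitude_vector_fit(d1, fit_config(n_poles = 2, dc_zero = FALSE,
                                              initial_pole_spread = c(0.5, 80)))
  expect_lt(relative_rmse(fit1, G1, f), 0.1)

  # the 4th-order brain transfer is recovered exactly from clean samples
  fx <- brain_plant_fixture()
  fc <- 1:100
  dd <- gain_samples(fc, Mod(frequency_response(fx$G, fc))^2)
  fit4 <- magnitude_vector_fit(dd, fit_config(n_poles = 4))
  expect_lt(relative_rmse(fit4, fx$G, fc), 1e-4)
})

test_that("constant magnitude data yields a static gain", {
  f <- 1:100
  d <- gain_samples(f, rep(1, 100))
  fit <- magnitude_vector_fit(d, fit_config(n_poles = 2, dc_zero = FALSE,
                                            allow_feedthrough = TRUE))
  resp <- Mod(frequency_response(fit, f))
  expect_equal(resp, rep(1, 100), tolerance = 1e-6)
})

test_that("relative complex RMSE penalizes magnitude and phase", {
  G <- random_stable_tf(seed = 9)
  f <- probe_grid(60)
  expect_equal(relative_rmse(G, G, f), 0)
  G11 <- transfer_function(1.1 * G$num, G$den)
  expect_equal(relative_rmse(G11, G, f), 10, tolerance = 1e-9)
  # a pure 90-degree rotation gives |e^{i pi/2} - 1| = sqrt(2) at every point
  rotated <- structure(G, class = "lti_tf")
  gf <- frequency_response(G, f) * exp(1i * pi / 2)
  rmse <- 100 * sqrt(mean(Mod((gf - frequency_response(G, f)) /
                                frequency_response(G, f))^2))
  expect_equal(rmse, 141.4214, tolerance = 1e-3)
})

test_that("fitted models are stable and minimum phase under noise", {
  for (seed in 1:5) {
    tr <- estimation_trial(seed)
    p <- tf_poles(tr$fit)
    expect_true(all(Re(p) < 0))
    z <- tf_zeros(tr$fit)
    expect_true(all(Re(z) <= 1e-9 * pmax(Mod(z), 1)))
  }
})

test_that("fitted phase tracks the true phase in the control band", {
  # at the standard protocol SNR the reconstructed phase should stay within
  # 15 degrees of the true phase over 5-60 Hz
  errs <- sapply(1:5, function(seed) {
    tr <- estimation_trial(seed)
    f <- 5:60
    fx <- brain_plant_fixture()
    ph <- Arg(frequency_response(tr$fit, f) / frequency_response(fx$G, f))
    max(abs(ph)) * 180 / pi
  })
  expect_lt(median(errs), 15)
})

test_that("non-convergence is flagged, not fatal", {
  set.seed(3)
  f <- 1:100
  # pathological data: pure noise floor
  d <- gain_samples(f, abs(rnorm(100, sd = 1e-3)) + 1e-6)
  fit <- magnitude_vector_fit(d, fit_config(n_poles = 4, n_iterations = 2))
  expect_true(is.list(attr(fit, "fit")))
  expect_true(is.logical(attr(fit, "fit")$converged))
  expect_error(
    magnitude_vector_fit(gain_samples(1:10, rep(1, 10)), fit_config(n_poles = 4)),
    "data points")
})
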