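test_that("the band-shaping filter evaluates to its weights at band centers", {
  # single band: exactly the weight at the natural frequency
  Hb <- build_filter(filter_band(23, 7, -0.4))
  expect_equal(frequency_response(Hb, 23), -0.4 + 0i, tolerance = 1e-12)

  # default two-band filter at 10 Hz: real part dominated by the alpha
  # weight, the gamma term contributing only a few percent
  H <- build_filter()
  v10 <- frequency_response(H, 10)
  expect_equal(Re(v10), 1, tolerance = 0.05)
  gamma_term <- frequency_response(build_filter(filter_band(40, 30, -0.5)), 10)
  expect_lt(abs(Re(gamma_term)), 0.05)

  # empty band list: the zero filter; H vanishes at DC and at infinity
  H0 <- build_filter(list())
  expect_equal(frequency_response(H0, c(0, 10, 100)), rep(0 + 0i, 3))
  expect_equal(Mod(frequency_response(H, c(0, 4000))), c(0, 0), tolerance = 1e-2)
})

test_that("controller synthesis solves the closed-loop design identity", {
  # H = 0 gives the zero controller
  fx <- brain_plant_fixture()
  K0 <- synthesize_controller(build_filter(list()), fx$G)
  expect_equal(K0$num, 0)

  # G = 1, H = 1: K = 1/2 by hand
  one <- transfer_function(1, 1)
  K <- synthesize_controller(transfer_function(1, 1), one)
  expect_equal(frequency_response(K, c(0, 5)), rep(0.5 + 0i, 2), tolerance = 1e-12)

  # exact plant: 1/(1 - G K) equals 1 + H to high accuracy on 1-100 Hz
  H <- build_filter()
  Ke <- synthesize_controller(H, fx$G)
  f <- seq(1, 100, by = 0.5)
  S <- closed_loop_response(fx$G, Ke)
  tgt <- 1 + frequency_response(H, f)
  expect_lt(max(Mod(frequency_response(S, f) - tgt) / Mod(tgt)), 1e-6)
  expect_true(attr(S, "stable"))

  # non-minimum-phase plants are refused
  Gnmp <- transfer_function(c(1, -10), c(1, 3, 2))
  expect_error(synthesize_controller(H, Gnmp), "right-half-plane")
})

test_that("closed-loop response identities hold", {
  G <- transfer_function(1, c(1, 1))
  expect_equal(frequency_response(closed_loop_response(G, transfer_function(0, 1)),
                                  c(0, 3)), rep(1 + 0i, 2))
  # constant loop gain 1/2: sensitivity 2
  half <- transfer_function(0.5, 1)
  one <- transfer_function(1, 1)
  expect_equal(frequency_response(closed_loop_response(one, half), 1), 2 + 0i,
               tolerance = 1e-12)
})

test_that("improper synthesized controllers get low-pass regularization", {
  # plant with relative degree 3 makes H / ((1+H) G) improper
  G3 <- transfer_function(1, Re(neuroloop:::poly_from_roots(c(-10, -20, -30))))
  K <- synthesize_controller(build_filter(), G3)
  expect_true(is_proper(K))
  expect_gte(attr(K, "n_lowpass"), 1L)
  # regularization barely affects gain in the band of interest (the added
  # poles do shift phase near 100 Hz)
  Kraw <- build_filter() / ((transfer_function(1, 1) + build_filter()) * G3)
  f <- 1:100
  expect_lt(max(abs(Mod(frequency_response(K, f)) /
                      Mod(frequency_response(Kraw, f)) - 1)), 0.15)
})

test_that("closed loop shapes band activities by |1+H|^2", {
  # ensemble over a few noise realizations, zero delay, exact model
  fx <- brain_plant_fixture()
  H <- build_filter()
  Kd <- discretize_tf(synthesize_controller(H, fx$G), fx$dt, method = "tustin")
  cl <- assemble_closed_loop(fx$plant, to_state_space(Kd), 0L)
  n <- 21000
  ratios <- sapply(1:6, function(s) {
    set.seed(s)
    noise <- cbind(rnorm(n, sd = sqrt(fx$pars$kappa_sq[1])),
                   rnorm(n, sd = sqrt(fx$pars$kappa_sq[2])))
    Y <- simulate_lti(cl, cbind(0, noise))
    y0 <- simulate_lti(fx$plant, cbind(0, noise))
    Pc <- welch_psd(signal_trace(Y[-(1:1000), 1], 1000))
    P0 <- welch_psd(signal_trace(y0$samples[-(1:1000)], 1000))
    c(band_activity(Pc, c(8, 12)) / band_activity(P0, c(8, 12)),
      band_activity(Pc, c(25, 55)) / band_activity(P0, c(25, 55)))
  })
  a_t <- mean(Mod(1 + frequency_response(H, 8:12))^2)
  g_t <- mean(Mod(1 + frequency_response(H, 25:55))^2)
  expect_equal(mean(ratios[1, ]), a_t, tolerance = 0.1)
  expect_equal(mean(ratios[2, ]), g_t, tolerance = 0.1)
  # the gamma suppression is genuinely below unity
  expect_lt(mean(ratios[2, ]), 0.6)
})
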