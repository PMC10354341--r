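test_that("frequency response matches a dense linear-algebra oracle", {
  # identity system
  one <- transfer_function(1, 1)
  expect_equal(frequency_response(one, c(0, 3, 17)), rep(1 + 0i, 3))

  # unit-peak bandpass evaluates to its weight at the natural frequency
  H1 <- build_filter(filter_band(10, 4, 1))
  expect_equal(frequency_response(H1, 10), 1 + 0i, tolerance = 1e-12)

  # linear brain model: tf response vs direct solve of (2*pi*i*f I - A) x = B
  fx <- brain_plant_fixture()
  f <- c(1, 10, 40)
  via_tf <- frequency_response(fx$G, f)
  via_solve <- vapply(f, function(ff) {
    x <- solve(2i * pi * ff * diag(4) - fx$model$A, fx$model$B[, 1])
    as.complex(fx$model$C %*% x)
  }, complex(1))
  expect_equal(via_tf, via_solve, tolerance = 1e-10)
})

test_that("state-space realization reproduces the transfer function", {
  # 1 / (s + 1)
  G <- transfer_function(1, c(1, 1))
  sys <- to_state_space(G)
  expect_equal(ss_order(sys), 1L)
  f <- c(0, 1, 5)
  expect_equal(frequency_response(sys, f), 1 / (2i * pi * f + 1),
               tolerance = 1e-12)

  # one-step predictor transfer: response at z = 1 is exactly 1
  a <- 0.5
  phi <- transfer_function(c(2 - a, -1), c(1, -a), domain = "z", dt = 1e-3)
  psys <- to_state_space(phi)
  expect_equal(ss_order(psys), 1L)
  expect_equal(Re(frequency_response(psys, 0)), 1, tolerance = 1e-14)

  # random stable 4-pole round trip on a 200-point grid
  G4 <- random_stable_tf(n_pairs = 2, seed = 7)
  sys4 <- to_state_space(G4)
  f <- probe_grid(200)
  r1 <- frequency_response(G4, f)
  r2 <- frequency_response(sys4, f)
  expect_lt(max(Mod(r1 - r2) / Mod(r1)), 1e-8)

  # improper functions are refused with the degree excess named
  expect_error(to_state_space(transfer_function(c(1, 0, 0), c(1, 1))),
               "improper")
})

test_that("simulation steps the exact discrete recursion", {
  sys <- discretize(to_state_space(transfer_function(1, c(1, 1))), 1e-3)

  # zero everything in, zero out
  out <- simulate_lti(sys, n_steps = 100)
  expect_equal(out$samples, rep(0, 100))

  # impulse response of 1/(s+1) sampled by ZOH decays geometrically
  u <- matrix(c(1, rep(0, 99)), ncol = 1)
  y <- simulate_lti(sys, u)$samples
  ratios <- y[3:50] / y[2:49]
  expect_equal(ratios, rep(exp(-1e-3), 48), tolerance = 1e-10)

  # rate mismatch is an error
  expect_error(simulate_lti(sys, signal_trace(rnorm(10), 500)), "rate")
})

test_that("ZOH discretization converges to the continuous response", {
  G <- random_stable_tf(n_pairs = 2, seed = 3)
  sys <- to_state_space(G)
  f <- c(5, 20, 60)
  ref <- frequency_response(G, f)
  errs <- vapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    d <- discretize(sys, dt)
    max(Mod(frequency_response(d, f) - ref) / Mod(ref))
  }, 0)
  expect_true(all(diff(errs) < 0))   # monotone decrease as dt shrinks
})

test_that("largest pole magnitude in dB flags stability", {
  dt <- 1e-3
  s1 <- state_space(diag(c(0.5, -0.2)), matrix(0, 2, 1), matrix(1, 1, 2),
                    domain = "discrete", dt = dt)
  expect_equal(max_pole_magnitude(s1), 20 * log10(0.5), tolerance = 1e-12)
  s2 <- state_space(matrix(1), matrix(1), matrix(1), domain = "discrete", dt = dt)
  expect_equal(max_pole_magnitude(s2), 0)
})

test_that("closed-loop assembly matches block-diagram algebra", {
  fx <- brain_plant_fixture()
  H <- build_filter()
  K <- synthesize_controller(H, fx$G)
  Kd <- discretize_tf(K, fx$dt, method = "tustin")
  f <- seq(1, 100, by = 2.5)

  # zero controller: output identically the resting path (transfer 1)
  open <- assemble_closed_loop(fx$plant, NULL, 0L)
  expect_equal(frequency_response(open, f, input = 1, output = 1),
               rep(1 + 0i, length(f)), tolerance = 1e-12)

  # zero delay, synthesized controller: y0 -> y equals 1/(1 - G K) pointwise
  cl <- assemble_closed_loop(fx$plant, to_state_space(Kd), 0L)
  Gd <- ss_to_tf(fx$plant, input = 1)
  L <- frequency_response(Gd, f) * frequency_response(Kd, f)
  expect_equal(frequency_response(cl, f, input = 1, output = 1),
               1 / (1 - L), tolerance = 1e-6)

  # five-step delay with a predictor chain: loop transfer equals
  # G K Phi(z)^5 z^-5 evaluated pointwise
  a <- 0.5; d <- 5L
  ctrl <- ss_series(to_state_space(Kd), make_predictor(a, d, fx$dt))
  cld <- assemble_closed_loop(fx$plant, ctrl, d)
  phi <- frequency_response(make_predictor(a, 1, fx$dt, as = "tf"), f)
  z <- exp(2i * pi * f * fx$dt)
  Ld <- frequency_response(Gd, f) * frequency_response(Kd, f) * phi^d * z^-d
  expect_equal(frequency_response(cld, f, input = 1, output = 1),
               1 / (1 - Ld), tolerance = 1e-6)
  # the delay-free loop realized 1 + H, which is stable
  expect_lt(max_pole_magnitude(cl), 0)
})

test_that("transfer-function algebra and minimal form behave", {
  G <- transfer_function(1, c(1, 1))
  K <- transfer_function(c(1, 0), c(1, 3, 2))   # s / ((s+1)(s+2))
  f <- probe_grid(50)
  expect_equal(frequency_response(G * K, f),
               frequency_response(G, f) * frequency_response(K, f),
               tolerance = 1e-12)
  expect_equal(frequency_response(G + K, f),
               frequency_response(G, f) + frequency_response(K, f),
               tolerance = 1e-12)
  # (s+1) cancellation is removed by the minimal form
  R <- transfer_function(c(1, 1), c(1, 3, 2))
  Rm <- tf_minreal(R)
  expect_equal(length(Rm$den) - 1L, 1L)
  expect_equal(frequency_response(Rm, f), frequency_response(R, f),
               tolerance = 1e-9)
})

test_that("system and trace serialization round-trips", {
  G <- random_stable_tf(seed = 5)
  p1 <- tempfile(fileext = ".json")
  write_system_json(G, p1)
  G2 <- read_system_json(p1)
  expect_equal(G$num, G2$num)
  expect_equal(G$den, G2$den)

  sys <- discretize(to_state_space(G), 1e-3)
  p2 <- tempfile(fileext = ".json")
  write_system_json(sys, p2)
  sys2 <- read_system_json(p2)
  expect_equal(sys$A, sys2$A)
  expect_equal(sys2$dt, 1e-3)

  tr <- signal_trace(sin(1:100 / 7), 250, label = "y")
  p3 <- tempfile(fileext = ".csv")
  write_signal_csv(tr, p3)
  tr2 <- read_signal_csv(p3)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-9)
  expect_equal(tr2$sampling_rate, 250, tolerance = 1e-6)

  psd <- psd_series(0:10, abs(rnorm(11)))
  p4 <- tempfile(fileext = ".csv")
  write_psd_csv(psd, p4)
  expect_equal(read_psd_csv(p4)$values, psd$values, tolerance = 1e-12)
})
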