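test_that("LQR gain matches a hand-iterated Riccati fixed point", {
  A <- matrix(0.9); B <- matrix(1); Q <- matrix(1); R <- matrix(1)
  X <- Q
  for (i in 1:500)
    X <- t(A) %*% X %*% A -
      t(A) %*% X %*% B %*% solve(R + t(B) %*% X %*% B) %*% t(B) %*% X %*% A + Q
  K_iter <- solve(R + t(B) %*% X %*% B, t(B) %*% X %*% A)
  expect_equal(lqr_gain(A, B, Q, R), K_iter, tolerance = 1e-10)

  # multivariate case: solution satisfies the Riccati equation residual
  set.seed(2)
  A2 <- matrix(rnorm(9), 3) * 0.4
  B2 <- matrix(rnorm(3), 3, 1)
  Q2 <- diag(3); R2 <- matrix(0.5)
  X2 <- solve_dare(A2, B2, Q2, R2)
  resid <- t(A2) %*% X2 %*% A2 - X2 -
    t(A2) %*% X2 %*% B2 %*% solve(R2 + t(B2) %*% X2 %*% B2) %*%
      t(B2) %*% X2 %*% A2 + Q2
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("the Smith structure removes the delay from the design loop", {
  fx <- brain_plant_fixture()
  Gm <- state_space(fx$plant$A, fx$plant$B[, 1, drop = FALSE], fx$plant$C,
                    fx$plant$D[, 1, drop = FALSE], "discrete", fx$dt)
  gains <- list(Kp = 5, Ki = 100)
  d <- 7L
  f <- c(1, 5, 10, 20, 40, 80)
  T_d <- frequency_response(
    assemble_tracking_loop(fx$plant, pi_with_smith(Gm, gains, d), d),
    f, input = 1, output = 1)
  T_0 <- frequency_response(
    assemble_tracking_loop(fx$plant, pi_with_smith(Gm, gains, 0L), 0L),
    f, input = 1, output = 1)
  expect_equal(T_d, T_0 * exp(-2i * pi * f * fx$dt * d), tolerance = 1e-10)

  # zero reference, zero noise, zero state: output stays zero
  loop <- assemble_tracking_loop(fx$plant, pi_with_smith(Gm, gains, d), d)
  Y <- simulate_lti(loop, matrix(0, 200, 3))
  expect_equal(max(abs(Y)), 0)

  # an unstable model is refused
  bad <- state_space(matrix(1.01), matrix(1), matrix(1), domain = "discrete",
                     dt = fx$dt)
  expect_error(pi_with_smith(bad, gains, 2L), "stable")
})

test_that("the reference restores target band content", {
  H <- build_filter()
  # identity when no shaping is requested
  res <- signal_trace(rnorm(5000), 1000)
  r0 <- make_reference(res, build_filter(list()))
  expect_equal(r0$samples, res$samples, tolerance = 1e-9)

  # a 10 Hz tone is amplified by |1 + H(2 pi i 10)|
  tone <- signal_trace(sin(2 * pi * 10 * (0:9999) / 1000), 1000)
  r <- make_reference(tone, H)
  amp <- sd(r$samples[3000:10000]) / sd(tone$samples[3000:10000])
  expect_equal(amp, Mod(1 + frequency_response(H, 10)), tolerance = 0.01)

  # broadband: reference PSD is |1+H|^2 times the source PSD per bin
  fx <- brain_plant_fixture()
  y0 <- simulate_linear_brain(fx$pars, 30, seed = 77)
  r2 <- make_reference(y0, H)
  Pr <- welch_psd(trim_transient(r2)); P0 <- welch_psd(trim_transient(y0))
  f <- 2:100
  ratio <- Pr$values[f + 1] / P0$values[f + 1]
  expect_equal(ratio, Mod(1 + frequency_response(H, f))^2, tolerance = 0.15)
})

test_that("tuned baselines stabilize the loop and run", {
  fx <- brain_plant_fixture()
  Gm <- state_space(fx$plant$A, fx$plant$B[, 1, drop = FALSE], fx$plant$C,
                    fx$plant$D[, 1, drop = FALSE], "discrete", fx$dt)
  H <- build_filter()
  f <- 1:100
  S0 <- psd_series(f, analytic_output_psd(fx$plant, c(0, sqrt(fx$pars$kappa_sq)), f))
  for (ty in c("pi", "lqg")) {
    tb <- tune_baseline(fx$plant, Gm, H, 5L, S0, sqrt(fx$pars$kappa_sq), ty)
    loop <- assemble_tracking_loop(fx$plant, tb$controller, 5L)
    expect_lt(max_pole_magnitude(loop), 0)
    # the same gains stabilize the delay-free nominal loop (sanity gate)
    ctrl0 <- if (ty == "pi") {
      pi_with_smith(Gm, list(Kp = tb$par$Kp, Ki = tb$par$Ki), 0L)
    } else {
      lqg_with_smith(Gm, list(q_y = tb$par$q_y, r_u = tb$par$r_u,
                              process_noise_cov = 1e-6,
                              measurement_noise_cov = 1e-9),
                     0L, ref_model = reference_model(fx$plant, H,
                                                     sqrt(fx$pars$kappa_sq)))
    }
    loop0 <- assemble_tracking_loop(fx$plant, ctrl0, 0L)
    expect_lt(max_pole_magnitude(loop0), 0)
  }
})
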