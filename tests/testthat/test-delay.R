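test_that("the predictor interpolates the negative delay at z = 1", {
  for (a in seq(-0.9, 0.9, by = 0.3)) {
    phi <- make_predictor(a, 1, 1e-3, as = "tf")
    pv <- function(p, x) { o <- 0; for (cc in p) o <- o * x + cc; o }
    pd <- function(p) { n <- length(p) - 1L; if (n == 0L) 0 else p[seq_len(n)] * (n:1) }
    val <- pv(phi$num, 1) / pv(phi$den, 1)
    slope <- (pv(pd(phi$num), 1) * pv(phi$den, 1) -
                pv(phi$num, 1) * pv(pd(phi$den), 1)) / pv(phi$den, 1)^2
    expect_equal(val, 1, tolerance = 1e-13)
    expect_equal(slope, 1, tolerance = 1e-12)
  }
  # a = 0 reduces to the linear extrapolator 2 - z^-1
  phi0 <- make_predictor(0, 1, 1e-3, as = "tf")
  expect_equal(phi0$num, c(2, -1))
  expect_equal(phi0$den, c(1, 0))
  expect_error(make_predictor(1.2, 1, 1e-3), "stable")
})

test_that("the predictor is one-step-ahead exact on ramps", {
  dt <- 1e-3
  pred <- make_predictor(0.5, 1, dt)
  ramp <- signal_trace((0:999) * dt, 1000)
  out <- simulate_lti(pred, ramp)
  k <- 900:998
  expect_lt(max(abs(out$samples[k] - ramp$samples[k + 1])), 1e-12)
})

test_that("predictor group delay is negative, approaching -dt per stage", {
  dt <- 1e-3
  for (a in c(-0.5, 0, 0.5)) {
    phi <- make_predictor(a, 1, dt, as = "tf")
    gd <- group_delay(phi, c(0.2, 2))
    expect_true(all(gd < 0))
    expect_equal(gd[1], -dt, tolerance = 0.05 * dt)
  }
})

test_that("chained predictors equal the single stage raised to a power", {
  dt <- 1e-3
  f <- c(1, 10, 40, 120)
  chain <- make_predictor(0.6, 5, dt)
  single <- frequency_response(make_predictor(0.6, 1, dt, as = "tf"), f)
  expect_equal(frequency_response(chain, f), single^5, tolerance = 1e-10)
})

test_that("filter weights rescale by the predictor band gain", {
  bands <- default_filter_bands()
  same <- rescale_filter_weights(bands, identity_system(1e-3))
  expect_equal(same[[1]]$c, 1)
  expect_equal(same[[2]]$c, -0.5)

  # a pure gain-2 stage halves every weight
  gain2 <- state_space(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0),
                       matrix(2, 1, 1), "discrete", 1e-3)
  halved <- rescale_filter_weights(bands, gain2)
  expect_equal(halved[[1]]$c, 0.5)
  expect_equal(halved[[2]]$c, -0.25)

  # chained predictor: two independent evaluation routes agree
  a <- 0.6; d <- 5; dt <- 1e-3
  chain_ss <- make_predictor(a, d, dt)
  res <- rescale_filter_weights(list(filter_band(40, 30, -0.5)), chain_ss)
  phi1 <- frequency_response(make_predictor(a, 1, dt, as = "tf"), 40)
  expect_equal(res[[1]]$c, -0.5 / Mod(phi1)^5, tolerance = 1e-10)
})

test_that("stability margin measures the distance to the critical point", {
  dt <- 1e-3
  zero_loop <- transfer_function(0, 1, "z", dt = dt)
  expect_equal(stability_margin(zero_loop), 1)
  const_half <- transfer_function(0.5, 1, "z", dt = dt)
  expect_equal(stability_margin(const_half), 0.5)
})

test_that("the stable predictor-pole region shrinks with delay", {
  fx <- brain_plant_fixture()
  sm <- stability_map(fx$plant, NULL, delays = c(3, 5, 10),
                      poles_a = seq(-0.95, 0.95, by = 0.1),
                      rescale_bands = default_filter_bands(), G_model = fx$G)
  widths <- sapply(c(3, 5, 10), function(d) {
    sum(sm$max_pole_db[sm$delay_steps == d] < 0)
  })
  expect_true(all(diff(widths) < 0))

  # poles below the stable interval destabilize the long-delay loop
  # (as a -> 1 the stage degenerates toward unity instead, so the lower
  # edge is where instability genuinely appears)
  sm_lo <- stability_map(fx$plant, NULL, delays = 10, poles_a = -0.5,
                         rescale_bands = default_filter_bands(), G_model = fx$G)
  expect_gte(sm_lo$max_pole_db, 0)

  # no delay, no predictor: stable for the plain synthesized loop
  Kd <- discretize_tf(synthesize_controller(build_filter(), fx$G), fx$dt,
                      method = "tustin")
  cl <- assemble_closed_loop(fx$plant, to_state_space(Kd), 0L)
  expect_lt(max_pole_magnitude(cl), 0)
})

test_that("predictor compensation shrinks delayed-loop band errors", {
  fx <- brain_plant_fixture()
  H <- build_filter()
  f <- 1:100
  S0 <- psd_series(f, analytic_output_psd(fx$plant, c(0, sqrt(fx$pars$kappa_sq)), f))
  tgtS <- Mod(1 + frequency_response(H, f))^2 * S0$values
  tgt_a <- sum(tgtS[8:12]); tgt_g <- sum(tgtS[25:55])
  d <- 5L
  Kd <- discretize_tf(synthesize_controller(H, fx$G), fx$dt, method = "tustin")

  errs <- function(loop) {
    Tf <- frequency_response(loop, f, input = 1, output = 1)
    S <- Mod(Tf)^2 * S0$values
    c(abs(sum(S[8:12]) - tgt_a) / tgt_a, abs(sum(S[25:55]) - tgt_g) / tgt_g)
  }
  plain <- errs(assemble_closed_loop(fx$plant, to_state_space(Kd), d))
  sel <- auto_predictor_pole(fx$plant, fx$G, default_filter_bands(), d,
                             resting_psd = S0)
  b2 <- rescale_filter_weights(default_filter_bands(),
                               make_predictor(sel$a, d, fx$dt, as = "tf"))
  K2 <- discretize_tf(synthesize_controller(build_filter(b2), fx$G), fx$dt,
                      method = "tustin")
  comp <- errs(assemble_closed_loop(
    fx$plant, ss_series(to_state_space(K2), make_predictor(sel$a, d, fx$dt)), d))
  expect_lt(comp[1], plain[1])
  expect_lt(comp[2], plain[2])
})
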