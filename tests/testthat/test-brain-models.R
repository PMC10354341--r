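test_that("the linear model state matrix follows the population equations", {
  pars <- linear_brain_params()
  A <- build_linear_model(pars)$A
  expect_equal(A[1, ], c((-1 + 1.15) / 0.005, -1.15 / 0.005, 0, 0))
  expect_equal(A[2, ], c(0.63 / 0.020, (-1 - 0.63) / 0.020, 0, 0))

  # no interactions: four decoupled leaky integrators
  dec <- build_linear_model(linear_brain_params(
    tau_e = 1, tau_i = 1, N11 = 1e-12, N21 = 1e-12, N12 = 1e-12, N22 = 1e-12,
    b = rep(1, 4)))
  expect_equal(dec$A, -diag(4), tolerance = 1e-9)

  # default parameters give a stable model
  expect_true(all(Re(ss_poles(build_linear_model(pars))) < 0))
})

test_that("the stimulation transfer has alpha and gamma resonances", {
  fx <- brain_plant_fixture()
  f <- seq(5, 60, by = 0.25)
  mag <- Mod(frequency_response(fx$G, f))
  n <- length(mag)
  peaks <- f[which(mag[2:(n - 1)] > mag[1:(n - 2)] &
                   mag[2:(n - 1)] >= mag[3:n]) + 1]
  expect_true(any(peaks >= 8 & peaks <= 12))    # alpha resonance
  expect_true(any(peaks >= 25 & peaks <= 55))   # gamma resonance
  # DC gain equals C (-A)^-1 B
  dc <- as.numeric(fx$model$C %*% solve(-fx$model$A, fx$model$B[, 1]))
  expect_equal(Re(frequency_response(fx$G, 0)), dc, tolerance = 1e-9)
})

test_that("resting spectra match the analytic noise-to-output spectrum", {
  fx <- brain_plant_fixture()
  f <- 1:100
  truth <- analytic_output_psd(fx$plant, c(0, sqrt(fx$pars$kappa_sq)), f)
  n_seeds <- 12
  ens <- sapply(seq_len(n_seeds), function(s) {
    welch_psd(simulate_linear_brain(fx$pars, 30, seed = 5000 + s))$values[f + 1]
  })
  m <- rowMeans(ens)
  se <- apply(ens, 1, sd) / sqrt(n_seeds)
  expect_true(mean(abs(m - truth) <= 3 * se) > 0.9)
})

test_that("pathological regimes weaken alpha and strengthen gamma", {
  # the healthy/pathological gamma contrast of the linear model is only a
  # few percent, so the full 50-seed ensemble is needed for significance
  seeds <- 1:50
  acts <- function(pars) t(sapply(seeds, function(s) {
    P <- welch_psd(simulate_linear_brain(pars, 30, seed = s))
    c(a = band_activity(P, c(8, 12)), g = band_activity(P, c(25, 55)))
  }))
  Ap <- acts(linear_brain_params("pathological"))
  Ah <- acts(linear_brain_params("healthy"))
  expect_lt(t.test(Ah[, "a"], Ap[, "a"], alternative = "greater")$p.value, 5e-4)
  expect_lt(t.test(Ah[, "g"], Ap[, "g"], alternative = "less")$p.value, 5e-4)

  # same directions for the cortico-thalamic stand-in
  ct_seeds <- 1:15
  ct_acts <- function(cond) t(sapply(ct_seeds, function(s) {
    P <- welch_psd(trim_transient(
      simulate_cortico_thalamic(cortico_thalamic_params(cond), 20, seed = s)))
    c(a = band_activity(P, c(8, 12)), g = band_activity(P, c(25, 55)))
  }))
  Cp <- ct_acts("pathological"); Ch <- ct_acts("healthy")
  expect_lt(t.test(Ch[, "a"], Cp[, "a"], alternative = "greater")$p.value, 5e-4)
  expect_lt(t.test(Ch[, "g"], Cp[, "g"], alternative = "less")$p.value, 5e-4)
})

test_that("the cortico-thalamic model rests at its equilibrium", {
  p <- cortico_thalamic_params()
  p$kappa_sq <- c(0, 0)
  y <- simulate_cortico_thalamic(p, 3, x0 = ct_equilibrium(p))
  expect_lt(diff(range(y$samples)), 1e-12)
})

test_that("halving the integration step leaves band activities unchanged", {
  p <- cortico_thalamic_params()
  ns <- asNamespace("neuroloop")
  set.seed(42)
  Tn <- 20000
  sdv <- ns$ct_noise_sd(p)
  noise <- matrix(0, Tn, 7)
  noise[, 1] <- rnorm(Tn, sd = sdv[1]); noise[, 5] <- rnorm(Tn, sd = sdv[2])
  y1 <- simulate_cortico_thalamic(p, 20, noise_matrix = noise)
  # same piecewise-constant noise path, integrated at half the step
  y2full <- simulate_cortico_thalamic(p, 20, dt = 5e-4,
                                      noise_matrix = noise[rep(1:Tn, each = 2), ])
  y2 <- signal_trace(y2full$samples[seq(2, 2 * Tn, by = 2)], 1000)
  P1 <- welch_psd(trim_transient(y1)); P2 <- welch_psd(trim_transient(y2))
  for (band in list(c(8, 12), c(25, 55))) {
    expect_equal(band_activity(P2, band) / band_activity(P1, band), 1,
                 tolerance = 0.02)
  }
})

test_that("small-input responses superpose approximately linearly", {
  p <- cortico_thalamic_params()
  u <- white_noise_input(15, sd = 0.005, seed = 91)
  u2 <- signal_trace(2 * u$samples, 1000)
  y0 <- simulate_cortico_thalamic(p, 15, seed = 7)
  y1 <- simulate_cortico_thalamic(p, 15, input = u, seed = 7)
  y2 <- simulate_cortico_thalamic(p, 15, input = u2, seed = 7)
  r1 <- y1$samples - y0$samples
  resid <- (y2$samples - y0$samples) - 2 * r1
  expect_lt(var(resid) / var(r1), 0.05)
})
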