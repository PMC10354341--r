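test_that("reports are bit-reproducible for a fixed master seed", {
  cfg <- experiment_config(n_trials = 2L, duration_s = 10, master_seed = 17L)
  r1 <- run_model_estimation(cfg)
  r2 <- run_model_estimation(cfg)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$summary, r2$summary)
})

test_that("estimation reports expose the acceptance-relevant scalars", {
  cfg <- experiment_config(n_trials = 3L, duration_s = 10, master_seed = 4L)
  rep <- run_model_estimation(cfg)
  expect_true(all(c("rmse_pct", "amplitude_ratio") %in% names(rep$summary)))
  expect_true(all(c("rmse_pct", "amplitude_ratio", "converged") %in%
                    names(rep$trials)))
  expect_true(is.finite(rep$summary$rmse_pct))
  expect_gte(rep$n_nonconverged, 0)
  # report serialization
  p <- tempfile(fileext = ".json")
  write_report_json(rep, p)
  parsed <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(parsed$summary$rmse_pct, rep$summary$rmse_pct)
  expect_true(file.exists(sub("\\.json$", ".csv", p)))
})

test_that("the closed-loop runner reports activities against targets", {
  cfg <- experiment_config(n_trials = 2L, duration_s = 8, master_seed = 9L)
  rep <- run_closed_loop(cfg)
  expect_true(all(c("alpha", "gamma", "u_amplitude", "alpha_target",
                    "gamma_target") %in% names(rep$summary)))
  expect_equal(rep$summary$n_unstable, 0)
  # zero delay, exact model: activities within a loose band of targets even
  # at this short duration
  expect_equal(rep$summary$alpha / rep$summary$alpha_target, 1, tolerance = 0.3)
  expect_equal(rep$summary$gamma / rep$summary$gamma_target, 1, tolerance = 0.3)
})

test_that("the delay sweep emits one diagnostics row per delay", {
  sw <- run_delay_sweep(experiment_config(), delays_ms = c(3, 5))
  expect_equal(sw$trials$delay_ms, c(3, 5))
  expect_true(all(is.finite(sw$trials$margin)))
  expect_true(all(sw$trials$max_pole_db < 0))
  expect_true(all(sw$trials$best_margin >= sw$trials$margin - 1e-12))
})
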