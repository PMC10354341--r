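#' Experiment configuration
#'
#' Bundles the protocol parameters shared by the experiment runners. The
#' defaults are the standard study conditions: 30 s traces at 1 kHz, white
#' noise stimulation of standard deviation 0.005, 50 trials, pathological
#' linear plant, 1 s transient discarded.
#'
#' @param model `"linear"` or `"cortico_thalamic"`.
#' @param condition plant condition (noise variances).
#' @param duration_s simulated duration per trace (>= 2 s).
#' @param input_sd white-noise stimulation standard deviation.
#' @param delay_ms feedback delay in milliseconds (integer multiple of `dt`).
#' @param predictor_pole predictor pole in `(-1, 1)` or `"auto"`.
#' @param bands target filter bands (list of [filter_band()]).
#' @param n_trials ensemble size (>= 1).
#' @param master_seed integer seed; trial `i` derives its seeds from it.
#' @param controller `"proposed"`, `"pi"` or `"lqg"`.
#' @param fit [fit_config()] used whenever a model is fitted.
#' @param dt simulation sampling time (s).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(model = c("linear", "cortico_thalamic"),
                              condition = "pathological",
                              duration_s = 30, input_sd = 0.005,
                              delay_ms = 0, predictor_pole = "auto",
                              bands = default_filter_bands(),
                              n_trials = 50L, master_seed = 1L,
                              controller = c("proposed", "pi", "lqg"),
                              fit = fit_config(), dt = 1e-3) {
  model <- match.arg(model)
  controller <- match.arg(controller)
  stopifnot(n_trials >= 1L, duration_s >= 2, input_sd >= 0,
            delay_ms >= 0, abs(delay_ms / 1000 / dt - round(delay_ms / 1000 / dt)) < 1e-9)
  structure(list(model = model, condition = condition,
                 duration_s = duration_s, input_sd = input_sd,
                 delay_ms = delay_ms, predictor_pole = predictor_pole,
                 bands = bands, n_trials = as.integer(n_trials),
                 master_seed = as.integer(master_seed),
                 controller = controller, fit = fit, dt = dt),
            class = "experiment_config")
}

trial_seed <- function(config, trial, offset) {
  (config$master_seed %% 100000L) * 19997L + trial * 101L + offset
}

exp_simulate_resting <- function(config, seed) {
  if (config$model == "linear")
    simulate_linear_brain(linear_brain_params(config$condition),
                          config$duration_s, seed = seed, dt = config$dt)
  else
    simulate_cortico_thalamic(cortico_thalamic_params(config$condition),
                              config$duration_s, seed = seed, dt = config$dt)
}

exp_simulate_stimulated <- function(config, input, seed) {
  if (config$model == "linear")
    simulate_linear_brain(linear_brain_params(config$condition),
                          config$duration_s, input = input, seed = seed,
                          dt = config$dt)
  else
    simulate_cortico_thalamic(cortico_thalamic_params(config$condition),
                              config$duration_s, input = input, seed = seed,
                              dt = config$dt)
}

exp_reference_response <- function(config) {
  if (config$model == "linear")
    analytic_transfer(build_linear_model(linear_brain_params(config$condition)))
  else
    NULL   # delay system: reference curve available only pointwise
}

ci95 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) <= 1L) return(NA_real_)
  1.96 * stats::sd(x) / sqrt(length(x))
}

#' Open-loop model-estimation experiment
#'
#' Per trial: simulate a resting trace and an independently driven
#' stimulated trace (white-noise input), estimate the three Welch spectra,
#' extract the squared plant gain by spectral subtraction, fit a rational
#' model by magnitude vector fitting, and score it against the reference
#' response (the analytic transfer function for the linear plant, the
#' linearized delay response for the cortico-thalamic plant) with the
#' relative complex RMSE. Trials whose fit does not converge are excluded
#' from the ensemble means and counted.
#'
#' @param config an [experiment_config()].
#' @param f_range fitting frequency range in Hz.
#' @return list of class `experiment_report` with per-trial data frame
#'   `trials`, ensemble `summary` (mean and 95% CI of RMSE and amplitude
#'   ratio), and `n_nonconverged`.
#' @export
run_model_estimation <- function(config = experiment_config(),
                                 f_range = c(1, 100)) {
  ref_tf <- exp_reference_response(config)
  ct_ref <- if (config$model == "cortico_thalamic")
    cortico_thalamic_params(config$condition) else NULL
  rows <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    u <- white_noise_input(config$duration_s, sd = config$input_sd,
                           seed = trial_seed(config, i, 1L), dt = config$dt)
    y0 <- exp_simulate_resting(config, trial_seed(config, i, 2L))
    y <- exp_simulate_stimulated(config, u, trial_seed(config, i, 3L))
    Py0 <- welch_psd(y0); Py <- welch_psd(y); Pu <- welch_psd(u)
    gs <- extract_gain(Py, Py0, Pu, f_range = f_range)
    fit <- magnitude_vector_fit(gs, config$fit)
    info <- attr(fit, "fit")
    gref <- if (!is.null(ref_tf)) frequency_response(ref_tf, gs$frequencies)
            else ct_linear_response(ct_ref, gs$frequencies)
    gfit <- frequency_response(fit, gs$frequencies)
    rmse <- 100 * sqrt(mean(Mod((gfit - gref) / gref)^2))
    rows[[i]] <- data.frame(trial = i,
                            rmse_pct = rmse,
                            amplitude_ratio = amplitude_ratio(Py, Py0),
                            converged = info$converged,
                            residual = info$residual,
                            n_floored = gs$n_floored)
  }
  trials <- do.call(rbind, rows)
  ok <- trials$converged
  summary <- list(
    rmse_pct = mean(trials$rmse_pct[ok]),
    rmse_pct_ci95 = ci95(trials$rmse_pct[ok]),
    amplitude_ratio = mean(trials$amplitude_ratio),
    amplitude_ratio_ci95 = ci95(trials$amplitude_ratio))
  structure(list(kind = "model_estimation", config = config, trials = trials,
                 summary = summary, n_nonconverged = sum(!ok)),
            class = "experiment_report")
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  cat("Experiment report (", x$kind, "), ", nrow(x$trials), " trials\n", sep = "")
  for (nm in names(x$summary))
    if (is.numeric(x$summary[[nm]]) && length(x$summary[[nm]]) == 1L)
      cat(sprintf("  %s: %.6g\n", nm, x$summary[[nm]]))
  invisible(x)
}

# Build the deployed proposed controller (synthesized from model G_tf,
# rescaled for the predictor chain when delay > 0) and the assembled loop.
build_proposed_loop <- function(plant, G_tf, bands, delay_steps,
                                predictor_pole, resting_psd = NULL) {
  dt <- plant$dt
  if (delay_steps == 0L) {
    K <- discretize_tf(synthesize_controller(build_filter(bands), G_tf), dt,
                       method = "tustin")
    ctrl <- to_state_space(K)
    a <- NULL
  } else {
    if (identical(predictor_pole, "auto")) {
      sel <- auto_predictor_pole(plant, G_tf, bands, delay_steps,
                                 resting_psd = resting_psd)
      a <- sel$a
    } else a <- as.numeric(predictor_pole)
    pred_tf <- make_predictor(a, delay_steps, dt, as = "tf")
    bands2 <- rescale_filter_weights(bands, pred_tf)
    K <- discretize_tf(synthesize_controller(build_filter(bands2), G_tf), dt,
                       method = "tustin")
    ctrl <- ss_series(to_state_space(K), make_predictor(a, delay_steps, dt))
  }
  loop <- assemble_closed_loop(plant, ctrl, delay_steps)
  list(loop = loop, controller = ctrl, K = K, a = a)
}

linear_plant_discrete <- function(config) {
  pars <- linear_brain_params(config$condition)
  list(plant = discretize(build_linear_model(pars), config$dt), pars = pars)
}

#' Closed-loop spectral-shaping experiment
#'
#' Runs the full loop on the linear plant for `n_trials` noise realizations
#' and reports alpha/gamma band activities of the closed-loop output against
#' the `(1 + H)`-shaped targets, plus the mean stimulation amplitude. The
#' plant model used for synthesis is either the exact transfer function
#' (`use_fitted = FALSE`) or a model fitted per trial from an estimation run
#' (`use_fitted = TRUE`). For the baseline controllers the same protocol
#' runs with reference tracking (independent resting realization shaped by
#' `1 + H`).
#'
#' @param config an [experiment_config()].
#' @param use_fitted fit the plant model per trial instead of using the
#'   exact transfer function.
#' @return an `experiment_report` with per-trial activities and `summary`.
#' @export
run_closed_loop <- function(config = experiment_config(), use_fitted = FALSE) {
  if (config$model != "linear")
    return(run_closed_loop_ct(config, use_fitted = use_fitted))
  lp <- linear_plant_discrete(config)
  plant <- lp$plant; pars <- lp$pars
  dt <- config$dt
  d <- as.integer(round(config$delay_ms / 1000 / dt))
  H <- build_filter(config$bands)
  f <- 1:100
  S0 <- psd_series(f, analytic_output_psd(plant, c(0, sqrt(pars$kappa_sq)), f))
  G_exact <- analytic_transfer(build_linear_model(pars))
  tgt <- target_band_activities(H, S0)

  n_steps <- round(config$duration_s / dt)
  trim <- round(1 / dt)
  Gm <- state_space(plant$A, plant$B[, 1, drop = FALSE], plant$C,
                    plant$D[, 1, drop = FALSE], "discrete", dt)
  baseline <- NULL
  if (config$controller != "proposed") {
    baseline <- tune_baseline(plant, Gm, H, d, S0, sqrt(pars$kappa_sq),
                              type = config$controller)
  }
  fixed_loop <- NULL
  if (config$controller == "proposed" && !use_fitted)
    fixed_loop <- build_proposed_loop(plant, G_exact, config$bands, d,
                                      config$predictor_pole, S0)

  rows <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    set.seed(trial_seed(config, i, 4L))
    noise <- cbind(stats::rnorm(n_steps, sd = sqrt(pars$kappa_sq[1])),
                   stats::rnorm(n_steps, sd = sqrt(pars$kappa_sq[2])))
    fit_rmse <- NA_real_
    if (config$controller == "proposed") {
      if (use_fitted) {
        fit_cfg <- config; fit_cfg$n_trials <- 1L
        fit_cfg$master_seed <- trial_seed(config, i, 7L)
        G_use <- fit_once(fit_cfg)
        fit_rmse <- relative_rmse(G_use, G_exact, 1:100)
        bl <- tryCatch(build_proposed_loop(plant, G_use, config$bands, d,
                                           config$predictor_pole, S0),
                       error = function(e) NULL)
      } else bl <- fixed_loop
      if (is.null(bl) || max_pole_magnitude(bl$loop) >= 0) {
        rows[[i]] <- data.frame(trial = i, alpha = NA, gamma = NA,
                                u_amplitude = NA, stable = FALSE,
                                fit_rmse_pct = fit_rmse)
        next
      }
      Y <- simulate_lti(bl$loop, cbind(0, noise))
    } else {
      set.seed(trial_seed(config, i, 5L))
      noise_r <- cbind(stats::rnorm(n_steps, sd = sqrt(pars$kappa_sq[1])),
                       stats::rnorm(n_steps, sd = sqrt(pars$kappa_sq[2])))
      y0r <- simulate_lti(plant, cbind(0, noise_r))
      r <- make_reference(y0r, H)
      loop <- assemble_tracking_loop(plant, baseline$controller, d)
      Y <- simulate_lti(loop, cbind(r$samples, noise))
    }
    Py <- welch_psd(signal_trace(Y[-seq_len(trim), 1], 1 / dt))
    Pu <- welch_psd(signal_trace(Y[-seq_len(trim), 2], 1 / dt))
    rows[[i]] <- data.frame(trial = i,
                            alpha = band_activity(Py, c(8, 12)),
                            gamma = band_activity(Py, c(25, 55)),
                            u_amplitude = mean_amplitude(Pu),
                            stable = TRUE,
                            fit_rmse_pct = fit_rmse)
  }
  trials <- do.call(rbind, rows)
  ok <- trials$stable
  summary <- list(
    alpha = mean(trials$alpha[ok]), alpha_ci95 = ci95(trials$alpha[ok]),
    gamma = mean(trials$gamma[ok]), gamma_ci95 = ci95(trials$gamma[ok]),
    u_amplitude = mean(trials$u_amplitude[ok]),
    u_amplitude_ci95 = ci95(trials$u_amplitude[ok]),
    alpha_target = tgt$alpha, gamma_target = tgt$gamma,
    alpha_error_pct = abs(mean(trials$alpha[ok]) - tgt$alpha) / tgt$alpha * 100,
    gamma_error_pct = abs(mean(trials$gamma[ok]) - tgt$gamma) / tgt$gamma * 100,
    n_unstable = sum(!ok))
  structure(list(kind = "closed_loop", config = config, trials = trials,
                 summary = summary),
            class = "experiment_report")
}

# band activities of the (1 + H)-shaped target spectrum
target_band_activities <- function(H, resting_psd) {
  f <- resting_psd$frequencies
  Sy <- Mod(1 + frequency_response(H, f))^2 * resting_psd$values
  tp <- psd_series(f, Sy)
  list(alpha = band_activity(tp, c(8, 12)), gamma = band_activity(tp, c(25, 55)))
}

# single estimation + fit, returning the fitted transfer function
fit_once <- function(config, f_range = c(1, 100)) {
  u <- white_noise_input(config$duration_s, sd = config$input_sd,
                         seed = trial_seed(config, 1L, 1L), dt = config$dt)
  y0 <- exp_simulate_resting(config, trial_seed(config, 1L, 2L))
  y <- exp_simulate_stimulated(config, u, trial_seed(config, 1L, 3L))
  gs <- extract_gain(welch_psd(y), welch_psd(y0), welch_psd(u), f_range = f_range)
  magnitude_vector_fit(gs, config$fit)
}

# closed loop on the cortico-thalamic plant: the controller is synthesized
# from a fitted model (there is no exact rational transfer) and the loop is
# simulated by stepping plant (nonlinear, Rcpp) and controller together.
run_closed_loop_ct <- function(config, use_fitted = TRUE) {
  dt <- config$dt
  d <- as.integer(round(config$delay_ms / 1000 / dt))
  H <- build_filter(config$bands)
  ctp <- cortico_thalamic_params(config$condition)
  f <- 1:100
  S0 <- ct_resting_psd(ctp, f)
  tgt <- target_band_activities(H, S0)
  n_steps <- round(config$duration_s / dt)
  trim <- round(1 / dt)

  rows <- vector("list", config$n_trials)
  fit_cfg <- config; fit_cfg$n_trials <- 1L
  for (i in seq_len(config$n_trials)) {
    fit_cfg$master_seed <- trial_seed(config, i, 7L)
    G_fit <- fit_once(fit_cfg)
    bl <- tryCatch({
      if (d == 0L) {
        K <- discretize_tf(synthesize_controller(H, G_fit), dt, method = "tustin")
        list(ctrl = to_state_space(K))
      } else {
        a <- if (identical(config$predictor_pole, "auto")) {
          # pole chosen on the fitted model with the estimated resting PSD
          sel <- auto_predictor_pole(
            discretize(to_state_space(G_fit), dt) |> ct_fake_noise(),
            G_fit, config$bands, d, resting_psd = S0)
          sel$a
        } else as.numeric(config$predictor_pole)
        pred_tf <- make_predictor(a, d, dt, as = "tf")
        bands2 <- rescale_filter_weights(config$bands, pred_tf)
        K <- discretize_tf(synthesize_controller(build_filter(bands2), G_fit),
                           dt, method = "tustin")
        list(ctrl = ss_series(to_state_space(K), make_predictor(a, d, dt)))
      }
    }, error = function(e) NULL)
    if (is.null(bl)) {
      rows[[i]] <- data.frame(trial = i, alpha = NA, gamma = NA,
                              u_amplitude = NA, stable = FALSE)
      next
    }
    out <- ct_closed_loop_sim(ctp, bl$ctrl, d, n_steps, dt,
                              seed = trial_seed(config, i, 4L))
    Py <- welch_psd(signal_trace(out$y[-seq_len(trim)], 1 / dt))
    Pu <- welch_psd(signal_trace(out$u[-seq_len(trim)], 1 / dt))
    rows[[i]] <- data.frame(trial = i,
                            alpha = band_activity(Py, c(8, 12)),
                            gamma = band_activity(Py, c(25, 55)),
                            u_amplitude = mean_amplitude(Pu),
                            stable = all(is.finite(out$y)))
  }
  trials <- do.call(rbind, rows)
  ok <- trials$stable
  summary <- list(
    alpha = mean(trials$alpha[ok]), alpha_ci95 = ci95(trials$alpha[ok]),
    gamma = mean(trials$gamma[ok]), gamma_ci95 = ci95(trials$gamma[ok]),
    u_amplitude = mean(trials$u_amplitude[ok]),
    alpha_target = tgt$alpha, gamma_target = tgt$gamma,
    resting_alpha = band_activity(S0, c(8, 12)),
    resting_gamma = band_activity(S0, c(25, 55)),
    n_unstable = sum(!ok))
  structure(list(kind = "closed_loop_ct", config = config, trials = trials,
                 summary = summary),
            class = "experiment_report")
}

# attach two dummy noise columns so auto_predictor_pole can assemble the
# fitted model as a plant (its objective only uses the y0 input path)
ct_fake_noise <- function(sys) {
  B <- cbind(sys$B[, 1, drop = FALSE], 0, 0)
  state_space(sys$A, B, sys$C, cbind(sys$D[, 1, drop = FALSE], 0, 0),
              "discrete", sys$dt)
}

# co-simulation of the nonlinear cortico-thalamic plant with a discrete
# controller and an input delay chain
ct_closed_loop_sim <- function(ctp, ctrl, delay_steps, n_steps, dt, seed) {
  sdv <- ct_noise_sd(ctp) * sqrt(1e-3 / dt)
  nz <- channel_noise(n_steps, sdv, seed)
  noise <- matrix(0, n_steps, 7); noise[, 1] <- nz[, 1]; noise[, 5] <- nz[, 2]
  x0 <- ct_equilibrium(ctp)
  res <- ct_closed_loop_cpp(ctp$pars, ct_input_column(ctp), ct_obs_row(ctp),
                            noise, as.numeric(x0), dt, n_steps,
                            ctrl$A, ctrl$B, ctrl$C, ctrl$D,
                            as.integer(delay_steps))
  list(y = res[, 1], u = res[, 2])
}

#' Delay sweep: stability and accuracy versus feedback delay
#'
#' For each delay, selects the predictor pole automatically, then reports the
#' robustness ceiling (largest achievable Nyquist margin over stable poles),
#' the deployed margin, the largest closed-loop pole, and the analytic
#' alpha/gamma activity errors of the deployed loop. Supplying
#' `model_tf` (e.g. a fitted model with known RMSE) makes the sweep use it
#' for synthesis while the true plant stays in the loop, quantifying
#' robustness to model errors.
#'
#' @param config an [experiment_config()] (linear model).
#' @param delays_ms integer delays in milliseconds.
#' @param model_tf optional `lti_tf` used for controller synthesis instead
#'   of the exact transfer function.
#' @return an `experiment_report` whose `trials` data frame has one row per
#'   delay: `delay_ms`, `a`, `margin`, `best_margin`, `max_pole_db`,
#'   `alpha_error_pct`, `gamma_error_pct`.
#' @export
run_delay_sweep <- function(config = experiment_config(), delays_ms = 1:12,
                            model_tf = NULL) {
  stopifnot(config$model == "linear")
  lp <- linear_plant_discrete(config)
  plant <- lp$plant; pars <- lp$pars
  dt <- config$dt
  H <- build_filter(config$bands)
  f <- 1:100
  S0 <- psd_series(f, analytic_output_psd(plant, c(0, sqrt(pars$kappa_sq)), f))
  G_syn <- if (is.null(model_tf))
    analytic_transfer(build_linear_model(pars)) else model_tf
  tgt <- target_band_activities(H, S0)
  rows <- vector("list", length(delays_ms))
  for (k in seq_along(delays_ms)) {
    d <- as.integer(round(delays_ms[k] / 1000 / dt))
    sel <- tryCatch(
      auto_predictor_pole(plant, G_syn, config$bands, d, resting_psd = S0),
      error = function(e) NULL)
    if (is.null(sel)) {
      rows[[k]] <- data.frame(delay_ms = delays_ms[k], a = NA, margin = NA,
                              best_margin = NA, max_pole_db = NA,
                              alpha_error_pct = NA, gamma_error_pct = NA)
      next
    }
    bl <- build_proposed_loop(plant, G_syn, config$bands, d, sel$a, S0)
    Tf <- frequency_response(bl$loop, f, input = 1, output = 1)
    Sy <- psd_series(f, Mod(Tf)^2 * S0$values)
    a_m <- band_activity(Sy, c(8, 12)); g_m <- band_activity(Sy, c(25, 55))
    rows[[k]] <- data.frame(delay_ms = delays_ms[k], a = sel$a,
                            margin = sel$margin,
                            best_margin = sel$best_margin,
                            max_pole_db = sel$max_pole_db,
                            alpha_error_pct = abs(a_m - tgt$alpha) / tgt$alpha * 100,
                            gamma_error_pct = abs(g_m - tgt$gamma) / tgt$gamma * 100)
  }
  trials <- do.call(rbind, rows)
  structure(list(kind = "delay_sweep", config = config, trials = trials,
                 summary = list(
                   margin_span = range(trials$best_margin, na.rm = TRUE),
                   max_gamma_error_pct = max(trials$gamma_error_pct, na.rm = TRUE))),
            class = "experiment_report")
}

#' Write an experiment report to JSON (plus per-trial CSV)
#'
#' @param report an `experiment_report`.
#' @param path output JSON path; the per-trial table goes to the same name
#'   with a `.csv` extension.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(kind = report$kind,
              config = report$config[setdiff(names(report$config),
                                             c("bands", "fit"))],
              summary = report$summary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  utils::write.csv(report$trials, sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}
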