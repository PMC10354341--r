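#' Parameters of the stand-in cortico-thalamic model
#'
#' A seven-population delayed neural mass model of the cortico-thalamic
#' feedback circuit, shipped as a documented synthetic stand-in: states
#' `(v, w, Ve, Vi, Vte, Vti, Vret)` are the mean activities of the
#' superficial cortical excitatory/inhibitory pair (layers I-III), the deep
#' cortical pair (layers IV-VI), the thalamic relay excitatory/inhibitory
#' pair, and the reticular population. Populations couple through `tanh`
#' rate functions; all cortico-thalamic and thalamo-cortical fibers share
#' one conduction delay `tau`. The superficial pair is a fast
#' excitatory-inhibitory loop resonating in the gamma band; the delayed
#' cortex-relay-cortex loop resonates in the alpha band. Stimulation enters
#' the four cortical populations only (`B = (b1, b2, b3, b4, 0, 0, 0)`), and
#' the observation reads the two excitatory cortical populations
#' (`C = (c1, 0, c3, 0, 0, 0, 0)`).
#'
#' The default parameter registry lives in
#' `inst/extdata/cortico_thalamic_standin.json`; healthy and pathological
#' conditions differ only in the driving-noise variances, in the same
#' pattern as the linear model (pathological: more gamma-channel, less
#' alpha-channel drive).
#'
#' @param condition `"pathological"` or `"healthy"`.
#' @param registry path to a JSON parameter registry (defaults to the
#'   packaged stand-in).
#' @return a list of class `ct_params` with elements `pars` (named numeric
#'   vector of couplings, time constants and delay), `b` (input couplings),
#'   `c_obs` (observation weights), `kappa_sq` (noise variances, channels =
#'   superficial v, deep Ve), `condition`.
#' @export
cortico_thalamic_params <- function(condition = c("pathological", "healthy"),
                                    registry = NULL) {
  condition <- match.arg(condition)
  if (is.null(registry))
    registry <- system.file("extdata", "cortico_thalamic_standin.json",
                            package = "neuroloop", mustWork = TRUE)
  reg <- jsonlite::read_json(registry, simplifyVector = TRUE)
  pars <- unlist(reg$dynamics)
  b <- as.numeric(reg$input_couplings)
  c_obs <- as.numeric(reg$observation_weights)
  kap <- as.numeric(reg$noise_variance[[condition]])
  stopifnot(length(b) == 4L, all(b > 0), length(c_obs) == 2L, all(c_obs > 0),
            length(kap) == 2L, all(kap >= 0), pars[["delay"]] >= 0)
  structure(list(pars = pars, b = b, c_obs = c_obs, kappa_sq = kap,
                 condition = condition),
            class = "ct_params")
}

#' @exportS3Method base::print
print.ct_params <- function(x, ...) {
  cat("Cortico-thalamic stand-in parameters (", x$condition, " condition)\n",
      "  conduction delay: ", x$pars[["delay"]] * 1000, " ms\n", sep = "")
  invisible(x)
}

ct_input_column <- function(params) {
  taus <- params$pars[c("tau_v", "tau_w", "tau_e", "tau_i")]
  c(params$b / as.numeric(taus), 0, 0, 0)
}

ct_obs_row <- function(params) {
  c(params$c_obs[1], 0, params$c_obs[2], 0, 0, 0, 0)
}

ct_noise_sd <- function(params) {
  # channel 1 drives the superficial (gamma) pair, channel 2 the thalamic
  # relay (the alpha-generating loop); scaled 1/tau like the linear model
  c(sqrt(params$kappa_sq[1]) / params$pars[["tau_v"]],
    sqrt(params$kappa_sq[2]) / params$pars[["tau_t"]])
}

#' Simulate the cortico-thalamic model
#'
#' Fourth-order Runge-Kutta integration with fixed 1 ms step; the delayed
#' state is read from a history ring buffer (linearly interpolated at half
#' steps) initialized by holding the initial state constant on
#' `[-tau, 0]`. Driving noise is Gaussian, independent per channel and per
#' step, added to the state derivative as a piecewise-constant input.
#' Divergence (non-finite state) raises an error naming the time.
#'
#' @param params a [cortico_thalamic_params()] object.
#' @param duration simulated duration in seconds.
#' @param input `NULL` for resting state, or a [signal_trace()] at `1 / dt`
#'   Hz (stimulation current; enters the cortical populations).
#' @param seed integer master seed (`NULL` to use the current RNG state).
#' @param dt integration step in seconds (default 1 ms).
#' @param x0 initial state; defaults to the resting equilibrium located by
#'   [ct_equilibrium()].
#' @param full_state return the full 7-column state matrix instead of the
#'   observed output.
#' @param noise_matrix optional `n_steps x 7` matrix of per-step noise values
#'   overriding the generated noise (e.g. a held noise path for step-size
#'   convergence studies).
#' @return a `signal_trace` of `y = C x` at `1 / dt` Hz (or a matrix when
#'   `full_state`).
#' @export
simulate_cortico_thalamic <- function(params = cortico_thalamic_params(),
                                      duration = 30, input = NULL,
                                      seed = NULL, dt = 1e-3, x0 = NULL,
                                      full_state = FALSE, noise_matrix = NULL) {
  stopifnot(inherits(params, "ct_params"), duration > 0)
  n_steps <- round(duration / dt)
  U <- if (is.null(input)) matrix(0, 0, 1) else {
    if (!is_signal_trace(input)) stop("input must be a signal_trace or NULL")
    if (!isTRUE(all.equal(input$sampling_rate, 1 / dt)))
      stop("input sampling rate must be ", 1 / dt, " Hz")
    if (length(input$samples) < n_steps) stop("input shorter than simulation")
    matrix(input$samples[seq_len(n_steps)], ncol = 1)
  }
  if (is.null(noise_matrix)) {
    # per-step noise follows the 1 kHz reference convention; at other steps
    # the per-step sd is scaled to keep the noise spectral density unchanged
    sdv <- ct_noise_sd(params) * sqrt(1e-3 / dt)
    noise <- matrix(0, n_steps, 7)
    nz <- channel_noise(n_steps, sdv, seed)
    noise[, 1] <- nz[, 1]
    noise[, 5] <- nz[, 2]
  } else {
    noise <- as.matrix(noise_matrix)
    stopifnot(nrow(noise) == n_steps, ncol(noise) == 7)
  }
  if (is.null(x0)) x0 <- ct_equilibrium(params)
  X <- ct_sim_cpp(params$pars, U, ct_input_column(params), noise,
                  as.numeric(x0), dt, n_steps)
  if (full_state) return(X)
  signal_trace(drop(X %*% ct_obs_row(params)), 1 / dt,
               label = if (is.null(input)) "y0" else "y")
}

# Drift field F(x, x_delayed) of the stand-in, used by the equilibrium
# search and the linearization; mirrors the C++ kernel.
ct_drift <- function(pars, x, xd) {
  p <- as.list(pars)
  with(p, c(
    (-x[1] + tanh(n_vv * x[1] - n_vw * x[2] + n_vt * xd[5])) / tau_v,
    (-x[2] + tanh(n_wv * x[1] - n_ww * x[2])) / tau_w,
    (-x[3] + tanh(n_ee * x[3] - n_ei * x[4] + n_et * xd[5] + n_ev * x[1])) / tau_e,
    (-x[4] + tanh(n_ie * x[3])) / tau_i,
    (-x[5] + tanh(n_te * xd[3] - n_tr * xd[7] - n_ti * x[6])) / tau_t,
    (-x[6] + tanh(n_it * x[7])) / tau_t,
    (-x[7] + tanh(n_re * xd[3] + n_rt * x[5])) / tau_r))
}

#' Resting equilibrium of the cortico-thalamic model
#'
#' Numerically locates a root of `F(x, x) = 0` by damped fixed-point
#' iteration from the origin (the `tanh` couplings make `x = 0` an exact
#' equilibrium of the default registry; user registries may shift it).
#'
#' @param params a [cortico_thalamic_params()] object.
#' @param tol convergence tolerance on the drift norm.
#' @return numeric length-7 state vector.
#' @export
ct_equilibrium <- function(params, tol = 1e-12) {
  x <- rep(0, 7)
  for (i in 1:200) {
    dx <- ct_drift(params$pars, x, x)
    if (max(abs(dx)) < tol) return(x)
    x <- x + 0.2 * dx * min(params$pars[c("tau_v", "tau_e", "tau_t", "tau_r")])
  }
  warning("equilibrium search did not fully converge; returning best iterate")
  x
}

#' Linearized transfer and resting spectrum of the cortico-thalamic model
#'
#' Linearizes the delayed drift around the resting equilibrium and evaluates
#' the exact frequency response of the delay system,
#' `C (2 pi i f I - J0 - Jd e^{-2 pi i f tau})^{-1} B`, for the stimulation
#' channel (`ct_linear_response`) and the analytic resting-state output
#' spectrum from the noise channels (`ct_resting_psd`). These serve as the
#' ground-truth reference curves when scoring fitted models: the true system
#' is infinite dimensional (delay), which a rational fit can only
#' approximate.
#'
#' @param params a [cortico_thalamic_params()] object.
#' @param f frequency grid in Hz.
#' @return `ct_linear_response`: complex vector; `ct_resting_psd`: a
#'   [psd_series()] (per 1 Hz bin, at the 1 kHz simulation rate).
#' @export
ct_linear_response <- function(params, f) {
  lin <- ct_linearize(params)
  B <- ct_input_column(params)
  C <- ct_obs_row(params)
  vapply(f, function(ff) {
    M <- 2i * pi * ff * diag(7) - lin$J0 - lin$Jd * exp(-2i * pi * ff * lin$tau)
    as.complex((C %*% solve(M, B))[1L])
  }, complex(1))
}

#' @rdname ct_linear_response
#' @param fs sampling rate (Hz) whose white-noise convention the spectrum
#'   follows.
#' @export
ct_resting_psd <- function(params, f, fs = 1000) {
  lin <- ct_linearize(params)
  sdv <- ct_noise_sd(params)
  Bn <- cbind(c(1, 0, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 1, 0, 0))
  C <- ct_obs_row(params)
  vals <- vapply(f, function(ff) {
    M <- 2i * pi * ff * diag(7) - lin$J0 - lin$Jd * exp(-2i * pi * ff * lin$tau)
    h <- C %*% solve(M, Bn)
    sum(Mod(h)^2 * sdv^2) / fs * ifelse(ff == 0, 1, 2)
  }, numeric(1))
  psd_series(f, vals)
}

# Jacobians of the drift with respect to the instantaneous and the delayed
# state, at the resting equilibrium (numerical differentiation).
ct_linearize <- function(params, eps = 1e-7) {
  x0 <- ct_equilibrium(params)
  J0 <- matrix(0, 7, 7); Jd <- matrix(0, 7, 7)
  f0 <- ct_drift(params$pars, x0, x0)
  for (j in 1:7) {
    e <- rep(0, 7); e[j] <- eps
    J0[, j] <- (ct_drift(params$pars, x0 + e, x0) - f0) / eps
    Jd[, j] <- (ct_drift(params$pars, x0, x0 + e) - f0) / eps
  }
  list(J0 = J0, Jd = Jd, tau = params$pars[["delay"]], x0 = x0)
}
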