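#' Parameters of the linear two-population brain model
#'
#' The model couples two excitatory/inhibitory neural population pairs. With
#' the default parameters the first pair resonates in the alpha band (about
#' 10 Hz) and the second in the gamma band (about 34 Hz). The `condition`
#' selects the driving-noise variances: the pathological state (the
#' psychosis-like regime with weak alpha and strong gamma) drives both pairs
#' with variance `1e-4 / n_neurons`; the healthy state drives the alpha pair
#' harder (`3.6e-4 / n_neurons`) and the gamma pair more weakly
#' (`2.5e-5 / n_neurons`).
#'
#' @param condition `"pathological"` or `"healthy"` (noise variances only).
#' @param tau_e,tau_i excitatory/inhibitory synaptic time constants (s),
#'   shared by both pairs.
#' @param N11,N21,N12,N22 interaction gains (> 0).
#' @param b input coupling constants, length 4 (> 0), one per population.
#' @param n_neurons population size scaling the noise variances.
#' @param kappa_sq optional length-2 noise variances overriding `condition`.
#' @return a list of class `linear_brain_params`.
#' @export
linear_brain_params <- function(condition = c("pathological", "healthy"),
                                tau_e = 0.005, tau_i = 0.020,
                                N11 = 1.15, N21 = 0.63,
                                N12 = 2.52, N22 = 6.6,
                                b = c(0.18, 0.18, 0.14, 0.14),
                                n_neurons = 1000,
                                kappa_sq = NULL) {
  condition <- match.arg(condition)
  if (is.null(kappa_sq)) {
    kappa_sq <- if (condition == "pathological") {
      c(1e-4, 1e-4) / n_neurons
    } else {
      c(3.6e-4, 2.5e-5) / n_neurons
    }
  }
  stopifnot(tau_e > 0, tau_i > 0, all(c(N11, N21, N12, N22) > 0),
            length(b) == 4L, all(b > 0),
            length(kappa_sq) == 2L, all(kappa_sq >= 0))
  structure(list(condition = condition, tau_e = tau_e, tau_i = tau_i,
                 N11 = N11, N21 = N21, N12 = N12, N22 = N22,
                 b = b, kappa_sq = kappa_sq),
            class = "linear_brain_params")
}

#' Build the linear brain model as a state-space system
#'
#' States are `(Ve1, Vi1, Ve2, Vi2)`. Input 1 is the stimulation current
#' (coupled through `b / tau`), inputs 2-3 are the white driving noises of the
#' two excitatory populations (coupled through `1 / tau_e`). The output is the
#' summed effective field potential `Ve1 - Vi1 + Ve2 - Vi2`.
#'
#' @param params a [linear_brain_params()] object.
#' @return a continuous-time `lti_ss` with 4 states, 3 inputs, 1 output, with
#'   the parameters attached as attribute `"params"`. A warning is emitted if
#'   the state matrix is unstable for user-supplied parameters.
#' @export
build_linear_model <- function(params = linear_brain_params()) {
  stopifnot(inherits(params, "linear_brain_params"))
  te <- params$tau_e; ti <- params$tau_i
  A <- matrix(0, 4, 4)
  A[1, 1] <- (-1 + params$N11) / te; A[1, 2] <- -params$N11 / te
  A[2, 1] <- params$N21 / ti;        A[2, 2] <- (-1 - params$N21) / ti
  A[3, 3] <- (-1 + params$N12) / te; A[3, 4] <- -params$N12 / te
  A[4, 3] <- params$N22 / ti;        A[4, 4] <- (-1 - params$N22) / ti
  Bu <- params$b / c(te, ti, te, ti)
  Bn <- cbind(c(1 / te, 0, 0, 0), c(0, 0, 1 / te, 0))
  sys <- state_space(A, cbind(Bu, Bn), matrix(c(1, -1, 1, -1), 1, 4))
  if (!is_stable(sys))
    warning("linear brain model is unstable for these parameters")
  attr(sys, "params") <- params
  sys
}

#' Analytic transfer function of a linear plant
#'
#' Exact rational transfer function `C (sI - A)^-1 B + D` of one input
#' channel of a continuous linear state-space model, obtained via the
#' Leverrier-Faddeev recursion. Serves as the ground-truth reference when
#' scoring fitted models.
#'
#' @param model a continuous-time `lti_ss` with one output.
#' @param input input channel index (1 = stimulation for brain models).
#' @return an `lti_tf` in the Laplace domain.
#' @export
analytic_transfer <- function(model, input = 1L) {
  stopifnot(is_state_space(model), model$domain == "continuous",
            nrow(model$C) == 1L)
  ss_to_tf(model, input = input)
}

#' Simulate the linear brain model
#'
#' Discretizes the model by zero-order hold at `dt` and integrates it driven
#' by its white noise sources and an optional stimulation input. Noise
#' sequences are independent per channel, with per-step standard deviation
#' `sqrt(kappa_sq)`, seeded from `seed` plus the channel index.
#'
#' @param params a [linear_brain_params()] object.
#' @param duration simulated duration in seconds.
#' @param input `NULL` for resting state, or a [signal_trace()] at `1 / dt` Hz.
#' @param seed integer master seed (`NULL` to use the current RNG state).
#' @param dt simulation sampling time in seconds (default 1 ms).
#' @param x0 initial state (default zero).
#' @return a `signal_trace` of the observed output at `1 / dt` Hz.
#' @export
simulate_linear_brain <- function(params = linear_brain_params(), duration = 30,
                                  input = NULL, seed = NULL, dt = 1e-3,
                                  x0 = NULL) {
  stopifnot(duration > 0)
  model <- build_linear_model(params)
  sysd <- discretize(model, dt)
  n_steps <- round(duration / dt)
  u <- if (is.null(input)) rep(0, n_steps) else {
    if (!is_signal_trace(input)) stop("input must be a signal_trace or NULL")
    if (!isTRUE(all.equal(input$sampling_rate, 1 / dt)))
      stop("input sampling rate must be ", 1 / dt, " Hz")
    if (length(input$samples) < n_steps)
      stop("input shorter than the simulation")
    input$samples[seq_len(n_steps)]
  }
  # per-step noise sd follows the 1 kHz reference convention; scaled to keep
  # the spectral density unchanged at other integration steps
  noise <- channel_noise(n_steps, sqrt(params$kappa_sq * 1e-3 / dt), seed)
  out <- simulate_lti(sysd, cbind(u, noise), x0 = x0)
  out$label <- if (is.null(input)) "y0" else "y"
  out
}

# One independent N(0, sd_j^2) sequence per channel, seeded from a master
# seed plus the channel index so resting/stimulated runs can share noise
# streams reproducibly.
channel_noise <- function(n_steps, sd, seed = NULL) {
  out <- matrix(0, n_steps, length(sd))
  for (j in seq_along(sd)) {
    if (!is.null(seed)) set.seed(seed + j)
    if (sd[j] > 0) out[, j] <- stats::rnorm(n_steps, sd = sd[j])
  }
  out
}

#' White-noise stimulation input
#'
#' Discrete Gaussian white noise at the loop rate, the probe signal of the
#' open-loop model-estimation protocol.
#'
#' @param duration duration in seconds.
#' @param sd standard deviation of the input samples.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param dt sampling time in seconds.
#' @return a `signal_trace`.
#' @export
white_noise_input <- function(duration, sd = 0.005, seed = NULL, dt = 1e-3) {
  n_steps <- round(duration / dt)
  if (!is.null(seed)) set.seed(seed)
  signal_trace(stats::rnorm(n_steps, sd = sd), 1 / dt, label = "u")
}
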