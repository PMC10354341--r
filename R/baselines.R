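#' Reference signal for tracking controllers
#'
#' Reference-tracking baselines need an explicit target signal. It is
#' generated from a pre-recorded pathological resting-state trace by applying
#' the band-restoring filter `1 + H` (discretized bilinearly at the trace
#' rate), so the reference has the desired alpha/gamma activities but carries
#' its own driving noise, independent of the loop's.
#'
#' @param resting a [signal_trace()] of resting activity (independent
#'   realization from the controlled plant's noise).
#' @param H target filter (`lti_tf`, continuous).
#' @return a `signal_trace` with attribute `"filter"` = `H`.
#' @export
make_reference <- function(resting, H) {
  stopifnot(is_signal_trace(resting), is_transfer_function(H))
  dt <- 1 / resting$sampling_rate
  oneH <- tf_constant(1, H) + H
  sys <- to_state_space(discretize_tf(oneH, dt, method = "tustin"))
  out <- simulate_lti(sys, matrix(resting$samples, ncol = 1))
  out$label <- "reference"
  attr(out, "filter") <- H
  out
}

#' Discrete algebraic Riccati equation
#'
#' Solves `X = A' X A - A' X B (R + B' X B)^-1 B' X A + Q` by the
#' structure-preserving doubling algorithm.
#'
#' @param A,B state and input matrices of the discrete system.
#' @param Q state cost (symmetric positive semidefinite).
#' @param R input cost (symmetric positive definite).
#' @param tol convergence tolerance.
#' @return the stabilizing solution `X`.
#' @export
solve_dare <- function(A, B, Q, R, tol = 1e-12) {
  A <- as.matrix(A); B <- as.matrix(B); Q <- as.matrix(Q); R <- as.matrix(R)
  n <- nrow(A)
  Ak <- A
  Gk <- B %*% solve(R, t(B))
  Hk <- Q
  for (i in 1:100) {
    W <- diag(n) + Gk %*% Hk
    Wi_A <- solve(W, Ak)
    An <- Ak %*% Wi_A
    Gn <- Gk + Ak %*% solve(W, Gk) %*% t(Ak)
    Hn <- Hk + t(Ak) %*% Hk %*% Wi_A
    if (max(abs(Hn - Hk)) <= tol * max(abs(Hn), 1)) return((Hn + t(Hn)) / 2)
    Ak <- An; Gk <- Gn; Hk <- Hn
  }
  warning("DARE doubling iteration did not fully converge")
  (Hk + t(Hk)) / 2
}

#' LQR and Kalman gains
#'
#' `lqr_gain` returns the state-feedback gain `K = (R + B'XB)^-1 B'XA` from
#' the DARE solution; `kalman_gain` returns the predictor-form estimator gain
#' `L = A P C' (R_v + C P C')^-1` from the dual DARE.
#'
#' @param A,B,C system matrices.
#' @param Q,R LQR costs.
#' @param Qw,Rv process and measurement noise covariances.
#' @return gain matrix.
#' @export
lqr_gain <- function(A, B, Q, R) {
  X <- solve_dare(A, B, Q, R)
  solve(as.matrix(R) + t(B) %*% X %*% B, t(B) %*% X %*% as.matrix(A))
}

#' @rdname lqr_gain
#' @export
kalman_gain <- function(A, C, Qw, Rv) {
  P <- solve_dare(t(A), t(C), Qw, Rv)
  A <- as.matrix(A); C <- as.matrix(C)
  A %*% P %*% t(C) %*% solve(as.matrix(Rv) + C %*% P %*% t(C))
}

#' PI tracking controller with a Smith predictor
#'
#' Builds the discrete controller mapping `(reference, measured y)` to the
#' stimulation `u`: a proportional-integral law acting on the tracking error
#' against the Smith-predicted undelayed output
#' `y_hat = G_model(u) + (y - G_model_delayed(u))`, which removes the known
#' loop delay from the design loop when the model is exact.
#'
#' @param G_model discrete strictly proper plant model (`lti_ss`, one input,
#'   one output), must be stable (the Smith structure runs it open loop).
#' @param gains list with `Kp` and `Ki` (1/s).
#' @param delay_steps known loop delay in samples.
#' @return a discrete `lti_ss` with two inputs `(r, y)` and one output `u`.
#' @export
pi_with_smith <- function(G_model, gains, delay_steps) {
  stopifnot(is_state_space(G_model), G_model$domain == "discrete")
  if (!is_stable(G_model))
    stop("Smith predictor requires a stable plant model")
  dt <- G_model$dt
  core <- pi_core(gains, dt)
  smith_wrap(core, G_model, delay_steps)
}

# PI law on (r, y_hat): u = Kp (r - y_hat) + Ki z, where z accumulates the
# error through a slightly leaky integrator (0.5 Hz corner). The plant is
# AC-coupled (zero DC gain), so a perfect integrator would random-walk the
# stimulation offset without affecting the output.
pi_core <- function(gains, dt, leak_hz = 0.5) {
  stopifnot(is.finite(gains$Kp), is.finite(gains$Ki))
  lam <- 1 - 2 * pi * leak_hz * dt
  A <- matrix(lam, 1, 1)
  B <- matrix(c(dt, -dt), 1, 2)            # z+ = lam z + dt (r - y_hat)
  C <- matrix(gains$Ki, 1, 1)
  D <- matrix(c(gains$Kp, -gains$Kp), 1, 2)
  state_space(A, B, C, D, "discrete", dt)
}

#' LQG tracking controller with a Smith predictor
#'
#' Linear-quadratic-Gaussian servo: a Kalman filter estimates the plant
#' state from the Smith-corrected measurement, a second Kalman filter
#' estimates the state of the generative model of the (stochastic, band
#' limited) reference from the measured reference, and a linear-quadratic
#' regulator designed on the joint system penalizes the tracking error
#' `y - r` and the input. All gains come from discrete algebraic Riccati
#' equations; the whole compensator is wrapped in the same Smith structure
#' as the PI baseline. Reference tracking through a feedforward of the
#' reference-model state is essential here: the reference lives in the
#' alpha/gamma bands, so integral action alone cannot follow it.
#'
#' @param G_model discrete strictly proper stable plant model (`lti_ss`).
#' @param config list with elements `q_y` (tracking-error weight), `r_u`
#'   (input weight), `process_noise_cov` (plant state-noise covariance,
#'   matrix or scalar multiple of identity) and `measurement_noise_cov`
#'   (scalar).
#' @param delay_steps known loop delay in samples.
#' @param ref_model discrete `lti_ss` shaping white noise into the reference
#'   (e.g. the resting-output model in series with `1 + H`), with attribute
#'   or entry of its own process noise; supply as list
#'   `list(sys = <lti_ss>, input_sd = <per-channel sd>)`.
#' @return a discrete `lti_ss` with two inputs `(r, y)` and one output `u`.
#' @export
lqg_with_smith <- function(G_model, config, delay_steps, ref_model) {
  stopifnot(is_state_space(G_model), G_model$domain == "discrete")
  if (!is_stable(G_model))
    stop("Smith predictor requires a stable plant model")
  dt <- G_model$dt
  A <- G_model$A; B <- G_model$B[, 1L, drop = FALSE]
  C <- G_model$C[1L, , drop = FALSE]
  n <- nrow(A)
  Rsys <- ref_model$sys
  stopifnot(is_state_space(Rsys), Rsys$domain == "discrete")
  Ar <- Rsys$A; Cr <- Rsys$C[1L, , drop = FALSE]
  nr <- nrow(Ar)
  # joint regulator design: states (x, x_r), input u, cost on (C x - C_r x_r)
  Aa <- rbind(cbind(A, matrix(0, n, nr)), cbind(matrix(0, nr, n), Ar))
  Ba <- rbind(B, matrix(0, nr, 1))
  Le <- cbind(C, -Cr)
  Qa <- config$q_y * (t(Le) %*% Le)
  Ka <- lqr_gain(Aa, Ba, Qa, matrix(config$r_u, 1, 1))
  Kx <- Ka[, seq_len(n), drop = FALSE]; Kr <- Ka[, n + seq_len(nr), drop = FALSE]
  Qw <- config$process_noise_cov
  if (length(Qw) == 1L) Qw <- diag(as.numeric(Qw), n)
  L <- kalman_gain(A, C, Qw, matrix(config$measurement_noise_cov, 1, 1))
  Qwr <- Rsys$B %*% diag(ref_model$input_sd^2, ncol(Rsys$B)) %*% t(Rsys$B)
  Lr <- kalman_gain(Ar, Cr, Qwr + diag(1e-18, nr),
                    matrix(config$measurement_noise_cov, 1, 1))
  # controller states (x_hat, x_r_hat); inputs (r, y_hat); output u
  # x_hat+   = A x_hat + B u + L (y_hat - C x_hat)
  # x_r_hat+ = A_r x_r_hat + L_r (r - C_r x_r_hat)
  # u        = -Kx x_hat - Kr x_r_hat
  Acl <- rbind(cbind(A - B %*% Kx - L %*% C, -B %*% Kr),
               cbind(matrix(0, nr, n), Ar - Lr %*% Cr))
  Bcl <- rbind(cbind(matrix(0, n, 1), L),
               cbind(Lr, matrix(0, nr, 1)))
  Ccl <- cbind(-Kx, -Kr)
  Dcl <- matrix(0, 1, 2)
  core <- state_space(Acl, Bcl, Ccl, Dcl, "discrete", dt)
  smith_wrap(core, G_model, delay_steps)
}

# Wrap a tracking core (inputs r, y_hat -> u) in the Smith structure:
# y_hat = y - model_delayed(u) + model(u). The model output is delayed by a
# chain of unit-delay states.
smith_wrap <- function(core, G_model, delay_steps) {
  d <- as.integer(delay_steps)
  dt <- core$dt
  A_m <- G_model$A; B_m <- G_model$B[, 1L, drop = FALSE]
  C_m <- G_model$C[1L, , drop = FALSE]
  if (any(abs(G_model$D[1L, 1L]) > 0)) stop("plant model must be strictly proper")
  nm <- nrow(A_m); nc <- ss_order(core)
  Ac <- core$A; Bc_r <- core$B[, 1L, drop = FALSE]; Bc_y <- core$B[, 2L, drop = FALSE]
  Cc <- core$C; Dc_r <- core$D[1L, 1L]; Dc_y <- core$D[1L, 2L]

  # states: x_c, x_m, q_1..q_d (delayed model outputs)
  n <- nc + nm + d
  im <- nc + seq_len(nm); iq <- nc + nm + seq_len(d)
  # y_hat = y + C_m x_m - q_d  (q_d = model output d steps ago; d = 0 -> y)
  yh_x <- c(rep(0, nc), C_m, rep(0, d))
  if (d > 0L) yh_x[iq[d]] <- yh_x[iq[d]] - 1
  else yh_x[im] <- yh_x[im] - C_m   # zero delay: correction cancels
  # u = Cc x_c + Dc_r r + Dc_y y_hat
  u_x <- c(Cc, rep(0, nm + d)) + Dc_y * yh_x
  u_r <- Dc_r; u_y <- Dc_y

  A <- matrix(0, n, n); Br <- matrix(0, n, 1); By <- matrix(0, n, 1)
  ic <- seq_len(nc)
  if (nc > 0L) {
    A[ic, ic] <- Ac
    A[ic, ] <- A[ic, ] + Bc_y %*% matrix(yh_x, 1)
    Br[ic, 1] <- Bc_r
    By[ic, 1] <- Bc_y
  }
  A[im, im] <- A_m
  A[im, ] <- A[im, ] + B_m %*% matrix(u_x, 1)
  Br[im, 1] <- Br[im, 1] + B_m[, 1] * u_r
  By[im, 1] <- By[im, 1] + B_m[, 1] * u_y
  if (d > 0L) {
    A[iq[1L], im] <- C_m
    if (d > 1L) for (j in 2:d) A[iq[j], iq[j - 1L]] <- 1
  }
  state_space(A, cbind(Br, By), matrix(u_x, 1), matrix(c(u_r, u_y), 1),
              "discrete", dt)
}

#' Assemble a reference-tracking closed loop
#'
#' Connects a plant (stimulation input first, then noise channels) with a
#' two-input tracking controller `(r, y) -> u`, the stimulation passing
#' through `delay_steps` unit delays. Inputs of the result are
#' `(r, noise...)`; outputs are `(y, u)`.
#'
#' @param plant discrete `lti_ss`, strictly proper in its first input.
#' @param controller discrete `lti_ss` with inputs `(r, y)` and output `u`.
#' @param delay_steps loop delay in samples.
#' @return a discrete `lti_ss` with attribute `"stable"`.
#' @export
assemble_tracking_loop <- function(plant, controller, delay_steps = 0L) {
  stopifnot(is_state_space(plant), is_state_space(controller),
            plant$domain == "discrete", controller$domain == "discrete",
            ncol(controller$B) == 2L)
  if (any(abs(plant$D[1L, ]) > 0)) stop("plant must be strictly proper")
  d <- as.integer(delay_steps)
  np <- ss_order(plant); nc <- ss_order(controller)
  m_noise <- ncol(plant$B) - 1L
  Ap <- plant$A; Bu <- plant$B[, 1L, drop = FALSE]
  Bw <- if (m_noise > 0L) plant$B[, -1L, drop = FALSE] else matrix(0, np, 0L)
  Cp <- plant$C[1L, , drop = FALSE]
  Ac <- controller$A; Bc_r <- controller$B[, 1L, drop = FALSE]
  Bc_y <- controller$B[, 2L, drop = FALSE]
  Cc <- controller$C[1L, , drop = FALSE]
  Dc_r <- controller$D[1L, 1L]; Dc_y <- controller$D[1L, 2L]

  n <- np + nc + d
  ip <- seq_len(np); ic <- np + seq_len(nc); iq <- np + nc + seq_len(d)
  u_x <- c(Dc_y * Cp, if (nc > 0L) Cc else numeric(0), rep(0, d))
  A <- matrix(0, n, n); Br <- matrix(0, n, 1); Bn <- matrix(0, n, m_noise)
  A[ip, ip] <- Ap
  if (nc > 0L) {
    A[ic, ic] <- Ac
    A[ic, ip] <- Bc_y %*% Cp
    Br[ic, 1] <- Bc_r
  }
  if (d > 0L) {
    A[iq[1L], ] <- u_x
    Br[iq[1L], 1] <- Dc_r
    if (d > 1L) for (j in 2:d) A[iq[j], iq[j - 1L]] <- 1
    A[ip, iq[d]] <- A[ip, iq[d]] + Bu[, 1]
  } else {
    A[ip, ] <- A[ip, ] + Bu %*% matrix(u_x, 1)
    Br[ip, 1] <- Br[ip, 1] + Bu[, 1] * Dc_r
  }
  if (m_noise > 0L) Bn[ip, ] <- Bw
  Cy <- matrix(c(Cp, rep(0, nc + d)), 1)
  Cu <- matrix(u_x, 1)
  Dy <- matrix(0, 1, 1 + m_noise)
  Du <- matrix(c(Dc_r, rep(0, m_noise)), 1)
  sys <- state_space(A, cbind(Br, Bn), rbind(Cy, Cu), rbind(Dy, Du),
                     "discrete", plant$dt)
  attr(sys, "stable") <- max_pole_magnitude(sys) < 0
  sys
}

#' Tune baseline controller gains by grid search
#'
#' Candidates are scored by the analytic power of the tracking error
#' `y - r` over the reference spectrum and the plant noise channels,
#' subject to closed-loop stability: a reference-tracking law realizes
#' "match the target activities as closely as possible without
#' destabilizing" by following its reference as closely as the loop allows.
#' (A band-activity objective degenerates here: because the reference
#' carries noise independent of the plant's, band activities alone are
#' minimized by switching the controller off.)
#'
#' @param plant discrete plant with noise channels.
#' @param G_model discrete plant model used inside the Smith structure.
#' @param H target filter (`lti_tf`).
#' @param delay_steps loop delay in samples.
#' @param resting_psd [psd_series()] of the resting output on an integer grid.
#' @param noise_sd per-channel plant noise standard deviations.
#' @param type `"pi"` or `"lqg"`.
#' @param grid named list of candidate vectors (`Kp`, `Ki` for PI; `q_y`,
#'   `r_u` for LQG).
#' @param ref_model reference generative model for the LQG servo (see
#'   [lqg_with_smith()]); when `NULL` it is built from the plant's noise
#'   channels in series with `1 + H`.
#' @return list with the winning controller (`controller`), its parameters
#'   (`par`), activity error (`error`) and stability flag.
#' @export
tune_baseline <- function(plant, G_model, H, delay_steps, resting_psd,
                          noise_sd, type = c("pi", "lqg"), grid = NULL,
                          ref_model = NULL) {
  type <- match.arg(type)
  if (type == "lqg" && is.null(ref_model))
    ref_model <- reference_model(plant, H, noise_sd)
  f <- resting_psd$frequencies
  Sr <- Mod(1 + frequency_response(H, f))^2 * resting_psd$values
  fs <- 1 / plant$dt
  if (is.null(grid)) {
    grid <- if (type == "pi")
      list(Kp = c(0.5, 1, 2, 5, 10, 20, 40), Ki = c(0, 10, 100, 1000))
    else
      list(q_y = 1, r_u = c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2))
  }
  combos <- expand.grid(grid)
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    par <- as.list(combos[i, , drop = FALSE])
    ctrl <- tryCatch({
      if (type == "pi")
        pi_with_smith(G_model, list(Kp = par$Kp, Ki = par$Ki), delay_steps)
      else
        lqg_with_smith(G_model,
                       list(q_y = par$q_y, r_u = par$r_u,
                            process_noise_cov = 1e-6,
                            measurement_noise_cov = 1e-9),
                       delay_steps, ref_model = ref_model)
    }, error = function(e) NULL)
    if (is.null(ctrl)) next
    loop <- assemble_tracking_loop(plant, ctrl, delay_steps)
    if (max_pole_magnitude(loop) >= -0.01) next
    # analytic tracking-error spectrum: S_e = |T_ry - 1|^2 S_r + noise terms
    Tr <- frequency_response(loop, f, input = 1, output = 1)
    Se <- Mod(Tr - 1)^2 * Sr
    for (j in seq_along(noise_sd)) {
      Tw <- frequency_response(loop, f, input = 1 + j, output = 1)
      w <- ifelse(f == 0, 1, 2)
      Se <- Se + w * Mod(Tw)^2 * noise_sd[j]^2 / fs
    }
    err <- sum(Se)
    if (is.null(best) || err < best$error)
      best <- list(controller = ctrl, par = par, error = err)
  }
  if (is.null(best)) stop("no stable ", type, " tuning found in the grid")
  best
}

#' Generative model of the tracking reference
#'
#' Discrete state-space system shaping the plant's white noise channels into
#' the reference signal: the noise-to-output part of the plant in series with
#' the band-restoring filter `1 + H`. Used by the LQG servo's reference
#' estimator.
#'
#' @param plant discrete plant with noise channels after the first input.
#' @param H target filter (`lti_tf`).
#' @param noise_sd per-channel noise standard deviations.
#' @return list with `sys` (an `lti_ss`, inputs = noise channels, output =
#'   reference) and `input_sd`.
#' @export
reference_model <- function(plant, H, noise_sd) {
  stopifnot(is_state_space(plant), ncol(plant$B) >= 2L)
  noise_part <- state_space(plant$A, plant$B[, -1L, drop = FALSE],
                            plant$C[1L, , drop = FALSE],
                            plant$D[1L, -1L, drop = FALSE],
                            "discrete", plant$dt)
  oneH <- to_state_space(discretize_tf(tf_constant(1, H) + H, plant$dt,
                                       method = "tustin"))
  list(sys = ss_series(noise_part, oneH), input_sd = noise_sd)
}
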