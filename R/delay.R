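#' One-step-ahead discrete predictor
#'
#' The stable one-pole/one-zero discrete system
#' `Phi(z) = ((2 - a) z - 1) / (z - a)` interpolating the ideal negative
#' one-step delay `z` at `z = 1` in value and slope: `Phi(1) = 1`,
#' `Phi'(1) = 1`. At low frequency its group delay approaches `-dt` per
#' stage (it anticipates its input by one sample). Delays of `d` steps are
#' compensated by chaining `d` copies in series.
#'
#' @param a predictor pole, real, `|a| < 1` (stability requirement).
#' @param steps number of chained one-step stages (>= 1).
#' @param dt sampling time in seconds.
#' @param as what to return: a discrete state-space chain or the single-stage
#'   transfer function.
#' @return an `lti_ss` (default) or `lti_tf` when `as = "tf"`.
#' @export
make_predictor <- function(a, steps = 1L, dt = 1e-3, as = c("ss", "tf")) {
  as <- match.arg(as)
  stopifnot(is.numeric(a), length(a) == 1L)
  if (abs(a) >= 1) stop("|a| must be < 1 for the predictor to be stable")
  stopifnot(steps >= 1L)
  tf1 <- predictor_tf(a, dt)
  if (as == "tf") {
    out <- tf1
    if (steps > 1L) for (i in seq_len(steps - 1L)) out <- out * tf1
    return(out)
  }
  stage <- to_state_space(tf1)
  out <- stage
  if (steps > 1L) for (i in seq_len(steps - 1L)) out <- ss_series(out, stage)
  out
}

predictor_tf <- function(a, dt) {
  transfer_function(c(2 - a, -1), c(1, -a), domain = "z", dt = dt)
}

#' Identity (pass-through) discrete system
#'
#' @param dt sampling time in seconds.
#' @return a zero-state `lti_ss` with unit feedthrough.
#' @export
identity_system <- function(dt = 1e-3) {
  state_space(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0),
              matrix(1, 1, 1), "discrete", dt)
}

#' Rescale filter-band weights for the predictor excess gain
#'
#' The chained predictor's magnitude slightly exceeds one inside the control
#' bands. Each band weight is divided by the predictor-chain magnitude at the
#' band's natural frequency, `c' = c / |Phi_total(exp(2 pi i f dt))|`, so the
#' realized closed-loop gain at the band centers matches the requested one.
#'
#' @param bands list of [filter_band()] objects.
#' @param predictor the predictor chain (`lti_ss` or `lti_tf`, discrete).
#' @return list of rescaled [filter_band()] objects.
#' @export
rescale_filter_weights <- function(bands, predictor) {
  if (inherits(bands, "filter_band")) bands <- list(bands)
  dt <- predictor$dt
  stopifnot(!is.null(dt))
  lapply(bands, function(bd) {
    if (bd$f >= 1 / (2 * dt)) stop("band frequency above Nyquist")
    gain <- Mod(frequency_response(predictor, bd$f))
    if (gain <= .Machine$double.eps)
      stop("predictor gain vanishes at ", bd$f, " Hz")
    filter_band(bd$f, bd$B, bd$c / gain)
  })
}

#' Assemble the delayed closed loop as one discrete system
#'
#' Realizes the positive-feedback neurostimulation loop: the plant output
#' feeds the controller (with the predictor chain in series), the controller
#' output passes through `delay_steps` unit-delay states, and drives the
#' plant input. Inputs of the assembled system are an additive output
#' disturbance (the resting-state activity path) followed by the plant's
#' noise channels; outputs are the closed-loop observation `y` and the
#' stimulation signal `u`.
#'
#' @param plant discrete `lti_ss`, strictly proper from its first input
#'   (no algebraic loop); input 1 is the stimulation channel, remaining
#'   inputs are noise channels.
#' @param controller discrete `lti_ss` mapping `y` to `u` (the predictor, if
#'   any, already in series), or `NULL` for open loop.
#' @param delay_steps nonnegative integer feedback delay in samples.
#' @return a discrete `lti_ss` with attribute `"stable"`; an unstable
#'   assembly is returned but flagged.
#' @export
assemble_closed_loop <- function(plant, controller = NULL, delay_steps = 0L) {
  stopifnot(is_state_space(plant), plant$domain == "discrete")
  if (is.null(controller)) controller <- zero_controller(plant$dt)
  stopifnot(is_state_space(controller), controller$domain == "discrete")
  if (!isTRUE(all.equal(plant$dt, controller$dt)))
    stop("plant and controller sampling times differ")
  stopifnot(delay_steps >= 0L)
  if (any(abs(plant$D[1L, ]) > 0) )
    stop("plant must be strictly proper (algebraic loop otherwise)")

  np <- ss_order(plant); nc <- ss_order(controller); d <- as.integer(delay_steps)
  m_noise <- ncol(plant$B) - 1L
  Ap <- plant$A; Bu <- plant$B[, 1L, drop = FALSE]
  Bw <- if (m_noise > 0L) plant$B[, -1L, drop = FALSE] else matrix(0, np, 0L)
  Cp <- plant$C[1L, , drop = FALSE]
  Ac <- controller$A; Bc <- controller$B; Cc <- controller$C
  Dc <- controller$D[1L, 1L]

  n <- np + nc + d
  A <- matrix(0, n, n); Bv <- matrix(0, n, 1L); Bn <- matrix(0, n, m_noise)
  ip <- seq_len(np); ic <- np + seq_len(nc); iq <- np + nc + seq_len(d)

  # y = Cp x_p + v ; u = Cc x_c + Dc y
  A[ip, ip] <- Ap
  if (nc > 0L) A[ic, ic] <- Ac
  if (nc > 0L) A[ic, ip] <- Bc %*% Cp
  if (nc > 0L) Bv[ic, 1L] <- Bc
  u_row_x <- c(Dc * Cp, if (nc > 0L) Cc else numeric(0), rep(0, d))
  u_row_v <- Dc
  if (d > 0L) {
    A[iq[1L], ] <- u_row_x
    Bv[iq[1L], 1L] <- u_row_v
    if (d > 1L) for (j in 2:d) A[iq[j], iq[j - 1L]] <- 1
    A[ip, iq[d]] <- A[ip, iq[d]] + Bu[, 1L]
  } else {
    A[ip, ] <- A[ip, ] + Bu %*% matrix(u_row_x, 1L)
    Bv[ip, 1L] <- Bv[ip, 1L] + Bu[, 1L] * u_row_v
  }
  if (m_noise > 0L) Bn[ip, ] <- Bw

  Cy <- matrix(c(Cp, rep(0, nc + d)), 1L)
  Cu <- matrix(u_row_x, 1L)
  Dy <- matrix(c(1, rep(0, m_noise)), 1L)
  Du <- matrix(c(u_row_v, rep(0, m_noise)), 1L)
  sys <- state_space(A, cbind(Bv, Bn), rbind(Cy, Cu), rbind(Dy, Du),
                     "discrete", plant$dt)
  attr(sys, "stable") <- max_pole_magnitude(sys) < 0
  sys
}

zero_controller <- function(dt) {
  state_space(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0),
              matrix(0, 1, 1), "discrete", dt)
}

#' Closed-loop stability map over predictor pole and delay
#'
#' For each combination of feedback delay (in steps) and predictor pole `a`,
#' assembles the loop with a chained predictor and records the magnitude of
#' the largest closed-loop pole in dB. Values below 0 dB mean the loop is
#' stable; the stable interval in `a` shrinks as the delay grows.
#'
#' @param plant discrete plant (`lti_ss`, stimulation input first).
#' @param controller_tf discrete controller transfer function (without the
#'   predictor), an `lti_tf`.
#' @param delays integer vector of delays in steps.
#' @param poles_a numeric grid of predictor poles in `(-1, 1)`.
#' @param rescale_bands optional list of [filter_band()]s; when supplied, the
#'   controller is re-synthesized per `a` from the rescaled filter via the
#'   supplied plant model `G_model`.
#' @param G_model continuous plant model (`lti_tf`) used with
#'   `rescale_bands`.
#' @return data frame with columns `delay_steps`, `a`, `max_pole_db`.
#' @export
stability_map <- function(plant, controller_tf, delays, poles_a,
                          rescale_bands = NULL, G_model = NULL) {
  stopifnot(is_state_space(plant), plant$domain == "discrete")
  dt <- plant$dt
  rows <- vector("list", length(delays) * length(poles_a))
  k <- 1L
  for (d in delays) {
    for (a in poles_a) {
      K_tf <- controller_tf
      if (!is.null(rescale_bands)) {
        pred_tf <- make_predictor(a, steps = max(d, 1L), dt = dt, as = "tf")
        bands2 <- rescale_filter_weights(rescale_bands, pred_tf)
        K_tf <- discretize_tf(synthesize_controller(build_filter(bands2), G_model), dt,
                              method = "tustin")
      }
      ctrl <- to_state_space(K_tf)
      if (d > 0L) ctrl <- ss_series(ctrl, make_predictor(a, steps = d, dt = dt))
      cl <- assemble_closed_loop(plant, ctrl, delay_steps = d)
      rows[[k]] <- data.frame(delay_steps = d, a = a,
                              max_pole_db = max_pole_magnitude(cl))
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}

#' Nyquist stability margin of a delayed open loop
#'
#' Shortest distance between the open-loop Nyquist locus and the critical
#' point, evaluated on a dense unit-circle grid. The neurostimulation loop
#' `y = y0 + G K y` is a positive feedback: its return ratio is `-L` with
#' `L(z) = G(z) K(z) Phi(z)^d z^-d`, so the classical distance of the
#' negated locus to `-1` equals the distance of `L` to `+1`, which is what
#' is computed. Larger margins mean more robustness to model uncertainty.
#'
#' @param open_loop discrete `lti_tf` or `lti_ss` of the full open loop
#'   (including predictor and delay states).
#' @param n_grid number of unit-circle evaluation points.
#' @return the margin (nonnegative scalar).
#' @export
stability_margin <- function(open_loop, n_grid = 4096L) {
  dt <- open_loop$dt
  stopifnot(!is.null(dt))
  f <- seq(0, 1 / (2 * dt), length.out = n_grid)
  L <- frequency_response(open_loop, f)
  min(Mod(L - 1), na.rm = TRUE)
}

#' Open loop of the delayed, predictor-compensated circuit
#'
#' Builds `L(z) = G(z) K(z) Phi(z)^d z^-d` as a discrete state-space chain
#' for Nyquist analysis. The state-space form stays numerically accurate at
#' long delays where expanded polynomial coefficients would degrade.
#'
#' @param G_d discrete plant (`lti_ss` with the stimulation input first, or
#'   an `lti_tf`).
#' @param K_d discrete controller (`lti_tf` or `lti_ss`).
#' @param a predictor pole (`NULL` for no predictor).
#' @param delay_steps feedback delay in steps.
#' @return an `lti_ss`.
#' @export
open_loop_system <- function(G_d, K_d, a = NULL, delay_steps = 0L) {
  if (is_transfer_function(K_d)) K_d <- to_state_space(K_d)
  dt <- K_d$dt
  L <- K_d
  if (delay_steps > 0L) {
    if (!is.null(a))
      L <- ss_series(L, make_predictor(a, steps = delay_steps, dt = dt))
    zdel <- to_state_space(
      transfer_function(1, c(1, rep(0, delay_steps)), "z", dt = dt))
    L <- ss_series(L, zdel)
  }
  if (is_transfer_function(G_d)) G_d <- to_state_space(G_d)
  plant1 <- state_space(G_d$A, G_d$B[, 1L, drop = FALSE], G_d$C[1L, , drop = FALSE],
                        G_d$D[1L, 1L, drop = FALSE], "discrete", dt)
  ss_series(L, plant1)
}

#' Automatic predictor-pole selection
#'
#' Grid search over the predictor pole `a`: candidates whose assembled closed
#' loop is not comfortably stable (largest pole at or above `stability_db`)
#' are discarded. Among the stable candidates, when a resting power spectrum
#' is supplied the pole minimizing the summed relative alpha- and gamma-band
#' activity error of the analytic closed-loop spectrum is chosen (the tuning
#' principle of matching target activities as closely as possible without
#' destabilizing the loop); otherwise the pole maximizing the Nyquist
#' stability margin is chosen.
#'
#' @param plant discrete plant (`lti_ss`, stimulation input first, noise
#'   channels after).
#' @param G_model continuous plant model (`lti_tf`) used to re-synthesize the
#'   controller from the rescaled filter for each candidate pole.
#' @param bands target filter bands (rescaled per candidate).
#' @param delay_steps feedback delay in steps (>= 1).
#' @param a_grid candidate poles.
#' @param stability_db required upper bound on the largest closed-loop pole
#'   (dB, default -0.05; the target-filter poles themselves sit near -0.11 dB
#'   at the default alpha bandwidth, bounding what any predictor can achieve).
#' @param resting_psd optional [psd_series()] of the resting output used for
#'   the activity-error objective.
#' @param alpha_band,gamma_band band edges in Hz for the activity objective.
#' @param margin_floor with the activity objective, only candidates whose
#'   margin is at least this fraction of the best achievable margin at this
#'   delay are considered (performance is not bought with fragility).
#' @return list with `a`, `margin`, `max_pole_db`, `best_margin` (the
#'   robustness ceiling over all stable candidates, with its pole
#'   `a_best_margin`), and `activity_error` when the spectrum objective is
#'   used; error if no stable candidate exists.
#' @export
auto_predictor_pole <- function(plant, G_model, bands, delay_steps,
                                a_grid = seq(-0.9, 0.9, by = 0.05),
                                stability_db = -0.05,
                                resting_psd = NULL,
                                alpha_band = c(8, 12), gamma_band = c(25, 55),
                                margin_floor = 0.9) {
  stopifnot(delay_steps >= 1L)
  dt <- plant$dt
  H0 <- build_filter(bands)
  # intrinsic pole floor: even the delay-free model-consistent loop retains
  # the filter poles and any lightly damped plant poles; the stability gate
  # cannot be stricter than halfway between that floor and 0 dB
  K0 <- discretize_tf(synthesize_controller(H0, G_model), dt, method = "tustin")
  cl0 <- assemble_closed_loop(plant, to_state_space(K0), 0L)
  floor_db <- max_pole_magnitude(cl0)
  gate_db <- if (floor_db > stability_db) floor_db / 2 else stability_db
  cands <- list()
  for (a in a_grid) {
    pred_tf <- make_predictor(a, steps = delay_steps, dt = dt, as = "tf")
    bands2 <- rescale_filter_weights(bands, pred_tf)
    K_tf <- discretize_tf(synthesize_controller(build_filter(bands2), G_model), dt,
                          method = "tustin")
    ctrl <- ss_series(to_state_space(K_tf),
                      make_predictor(a, steps = delay_steps, dt = dt))
    cl <- assemble_closed_loop(plant, ctrl, delay_steps = delay_steps)
    mp <- max_pole_magnitude(cl)
    if (mp >= gate_db) next
    cand <- list(a = a, max_pole_db = mp,
                 margin = stability_margin(
                   open_loop_system(plant, K_tf, a, delay_steps)))
    if (!is.null(resting_psd))
      cand$activity_error <- closed_loop_activity_error(
        cl, H0, resting_psd, alpha_band, gamma_band)
    cands[[length(cands) + 1L]] <- cand
  }
  if (length(cands) == 0L)
    stop("no predictor pole in the grid keeps the closed loop stable at ",
         delay_steps, " steps of delay")
  margins <- vapply(cands, `[[`, 0, "margin")
  i_rob <- which.max(margins)
  if (is.null(resting_psd)) {
    best <- cands[[i_rob]]
  } else {
    ok <- which(margins >= margin_floor * margins[i_rob])
    errs <- vapply(cands[ok], `[[`, 0, "activity_error")
    best <- cands[[ok[which.min(errs)]]]
  }
  best$best_margin <- margins[i_rob]
  best$a_best_margin <- cands[[i_rob]]$a
  best
}

# Summed relative alpha/gamma activity error of the analytic closed-loop
# spectrum |T_{y0->y}|^2 S_y0y0 against the (1 + H)-shaped target.
closed_loop_activity_error <- function(cl, H, resting_psd,
                                       alpha_band = c(8, 12),
                                       gamma_band = c(25, 55)) {
  f <- resting_psd$frequencies
  Tf <- frequency_response(cl, f, input = 1, output = 1)
  if (any(!is.finite(Tf))) return(Inf)
  S <- psd_series(f, Mod(Tf)^2 * resting_psd$values)
  tgt <- psd_series(f, Mod(1 + frequency_response(H, f))^2 * resting_psd$values)
  err <- 0
  for (band in list(alpha_band, gamma_band)) {
    m <- band_activity(S, band); tv <- band_activity(tgt, band)
    err <- err + abs(m - tv) / tv
  }
  err
}
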