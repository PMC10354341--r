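#' State-space systems
#'
#' Constructs a linear time-invariant state-space system
#' `x' = A x + B u, y = C x + D u` (continuous) or
#' `x[k+1] = A x[k] + B u[k], y[k] = C x[k] + D u[k]` (discrete with sampling
#' time `dt`).
#'
#' @param A,B,C,D system matrices (coerced to matrices; `D` defaults to zero).
#' @param domain `"continuous"` or `"discrete"`.
#' @param dt sampling time in seconds, required for discrete systems.
#' @return an object of class `lti_ss`.
#' @export
state_space <- function(A, B, C, D = NULL,
                        domain = c("continuous", "discrete"), dt = NULL) {
  domain <- match.arg(domain)
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (nrow(B) != n) stop("B must have as many rows as A")
  if (ncol(C) != n) stop("C must have as many columns as A")
  if (is.null(D)) D <- matrix(0, nrow(C), ncol(B))
  D <- as.matrix(D)
  if (nrow(D) != nrow(C) || ncol(D) != ncol(B))
    stop("D must be ", nrow(C), " x ", ncol(B))
  if (domain == "discrete") {
    if (is.null(dt) || !is.finite(dt) || dt <= 0)
      stop("discrete systems require a strictly positive sampling time `dt`")
  } else {
    dt <- NULL
  }
  structure(list(A = A, B = B, C = C, D = D, domain = domain, dt = dt),
            class = "lti_ss")
}

#' @exportS3Method base::print
print.lti_ss <- function(x, ...) {
  cat("State-space system (", x$domain,
      if (x$domain == "discrete") sprintf(", dt = %g s", x$dt) else "",
      "): ", nrow(x$A), " states, ", ncol(x$B), " inputs, ",
      nrow(x$C), " outputs\n", sep = "")
  invisible(x)
}

#' @rdname state_space
#' @param x object to test.
#' @export
is_state_space <- function(x) inherits(x, "lti_ss")

ss_order <- function(sys) nrow(sys$A)

#' State-space realization of a transfer function
#'
#' Builds the controllable canonical realization of a proper single-input
#' single-output rational transfer function. The frequency response of the
#' result matches the input on any probe grid to near machine precision.
#'
#' @param tf a proper `lti_tf`.
#' @return an `lti_ss` in the same domain.
#' @export
to_state_space <- function(tf) {
  stopifnot(is_transfer_function(tf))
  deg <- tf_degree(tf)
  if (deg["num"] > deg["den"])
    stop("transfer function is improper: numerator degree exceeds denominator degree by ",
         deg["num"] - deg["den"],
         "; append low-pass factors (see synthesize_controller) before realization")
  n <- as.integer(deg["den"])
  den <- tf$den                              # monic, length n + 1
  num <- c(rep(0, n + 1L - length(tf$num)), tf$num)
  d <- num[1L]                               # feedthrough
  b <- num[-1L] - d * den[-1L]               # strictly proper remainder
  domain <- if (tf$domain == "s") "continuous" else "discrete"
  if (n == 0L)
    return(state_space(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0),
                       matrix(d, 1, 1), domain, tf$dt))
  A <- rbind(-den[2:(n + 1L)],
             if (n > 1L) cbind(diag(1, n - 1L), 0))
  B <- matrix(c(1, rep(0, n - 1L)), n, 1)
  C <- matrix(b, 1, n)
  state_space(A, B, C, matrix(d, 1, 1), domain, tf$dt)
}

#' @export
frequency_response.lti_ss <- function(sys, f, input = 1L, output = 1L, ...) {
  stopifnot(all(f >= 0))
  if (sys$domain == "discrete" && any(f > 1 / (2 * sys$dt) + 1e-9))
    stop("frequencies above the Nyquist frequency ", 1 / (2 * sys$dt), " Hz")
  n <- ss_order(sys)
  pts <- if (sys$domain == "continuous") 2i * pi * f else exp(2i * pi * f * sys$dt)
  B <- sys$B[, input, drop = FALSE]
  C <- sys$C[output, , drop = FALSE]
  D <- sys$D[output, input]
  vapply(pts, function(x) {
    if (n == 0L) return(as.complex(D))
    sol <- tryCatch(solve(diag(x, n) - sys$A, B), error = function(e) NULL)
    if (is.null(sol)) return(NA_complex_)
    as.complex((C %*% sol)[1L] + D)
  }, complex(1))
}

#' Zero-order-hold discretization
#'
#' Discretizes a continuous-time state-space system at sampling time `dt` via
#' the matrix exponential of the augmented `[A B; 0 0]` block, i.e. inputs are
#' held constant over each step.
#'
#' @param sys a continuous-time `lti_ss`.
#' @param dt sampling time in seconds.
#' @return a discrete-time `lti_ss`.
#' @export
discretize <- function(sys, dt) {
  stopifnot(is_state_space(sys))
  if (sys$domain == "discrete") {
    if (!isTRUE(all.equal(sys$dt, dt))) stop("system is already discrete at dt = ", sys$dt)
    return(sys)
  }
  n <- ss_order(sys); m <- ncol(sys$B)
  M <- rbind(cbind(sys$A, sys$B), matrix(0, m, n + m))
  E <- as.matrix(Matrix::expm(M * dt))
  state_space(E[seq_len(n), seq_len(n), drop = FALSE],
              E[seq_len(n), n + seq_len(m), drop = FALSE],
              sys$C, sys$D, "discrete", dt)
}

#' Time-domain simulation of a discrete LTI system
#'
#' Steps `x[k+1] = A x[k] + B u[k]`, `y[k] = C x[k] + D u[k]`. Continuous
#' systems must be discretized with [discretize()] first. Inputs may be given
#' as a matrix (one column per input channel), a [signal_trace()], or a list
#' of signal traces; their sampling rate must equal `1 / dt`.
#'
#' @param sys a discrete-time `lti_ss`.
#' @param input input samples: matrix `T x m`, `signal_trace`, or list of
#'   traces (one per channel).
#' @param x0 initial state (defaults to zero).
#' @param n_steps number of steps when `input` is `NULL` (zero input).
#' @return a `signal_trace` for single-output systems, otherwise a `T x p`
#'   matrix of outputs.
#' @export
simulate_lti <- function(sys, input = NULL, x0 = NULL, n_steps = NULL) {
  stopifnot(is_state_space(sys))
  if (sys$domain != "discrete")
    stop("simulate_lti() needs a discrete system; call discretize() first")
  m <- ncol(sys$B)
  U <- coerce_input_matrix(input, m, sys$dt, n_steps)
  if (is.null(x0)) x0 <- rep(0, ss_order(sys))
  stopifnot(length(x0) == ss_order(sys))
  Y <- dlti_sim_cpp(sys$A, sys$B, sys$C, sys$D, U, as.numeric(x0))
  if (ncol(Y) == 1L)
    signal_trace(Y[, 1L], sampling_rate = 1 / sys$dt, label = "y")
  else Y
}

coerce_input_matrix <- function(input, m, dt, n_steps) {
  fs <- 1 / dt
  if (is.null(input)) {
    if (is.null(n_steps)) stop("either `input` or `n_steps` must be given")
    return(matrix(0, n_steps, m))
  }
  if (is_signal_trace(input)) input <- list(input)
  if (is.list(input)) {
    for (tr in input) {
      if (!is_signal_trace(tr)) stop("inputs must be signal traces")
      if (!isTRUE(all.equal(tr$sampling_rate, fs)))
        stop("input sampling rate ", tr$sampling_rate,
             " Hz does not match the system rate ", fs, " Hz")
    }
    input <- do.call(cbind, lapply(input, function(tr) tr$samples))
  }
  U <- as.matrix(input)
  if (ncol(U) != m) stop("expected ", m, " input channels, got ", ncol(U))
  U
}

#' System poles and stability
#'
#' `ss_poles()` returns the eigenvalues of the state matrix.
#' `max_pole_magnitude()` returns the magnitude of the largest discrete-time
#' pole in dB (`20 log10 max |eig(A)|`); negative values mean the system is
#' asymptotically stable.
#'
#' @param sys an `lti_ss`.
#' @return `ss_poles`: complex vector; `max_pole_magnitude`: scalar (dB).
#' @export
ss_poles <- function(sys) {
  if (ss_order(sys) == 0L) return(complex(0))
  eigen(sys$A, only.values = TRUE)$values
}

#' @rdname ss_poles
#' @export
max_pole_magnitude <- function(sys) {
  stopifnot(is_state_space(sys), sys$domain == "discrete")
  p <- ss_poles(sys)
  if (length(p) == 0L) return(-Inf)
  20 * log10(max(Mod(p)))
}

is_stable <- function(sys) {
  p <- ss_poles(sys)
  if (length(p) == 0L) return(TRUE)
  if (sys$domain == "continuous") all(Re(p) < 0) else all(Mod(p) < 1 - 1e-9)
}

#' Series connection of state-space systems
#'
#' Output of `sys1` feeds the input of `sys2` (`sys2 o sys1`).
#'
#' @param sys1,sys2 `lti_ss` systems in the same domain (matching `dt`).
#' @return an `lti_ss`.
#' @export
ss_series <- function(sys1, sys2) {
  stopifnot(is_state_space(sys1), is_state_space(sys2),
            sys1$domain == sys2$domain)
  if (sys1$domain == "discrete" && !isTRUE(all.equal(sys1$dt, sys2$dt)))
    stop("sampling times differ")
  n1 <- ss_order(sys1); n2 <- ss_order(sys2)
  A <- rbind(cbind(sys1$A, matrix(0, n1, n2)),
             cbind(sys2$B %*% sys1$C, sys2$A))
  B <- rbind(sys1$B, sys2$B %*% sys1$D)
  C <- cbind(sys2$D %*% sys1$C, sys2$C)
  D <- sys2$D %*% sys1$D
  state_space(A, B, C, D, sys1$domain, sys1$dt)
}

#' Discrete Lyapunov equation
#'
#' Solves `P = A P A' + Q` for a Schur-stable `A` by doubling iteration.
#' Used for stationary state covariances of noise-driven discrete systems.
#'
#' @param A square stable matrix.
#' @param Q symmetric positive semidefinite matrix.
#' @return the solution matrix `P`.
#' @export
solve_dlyap <- function(A, Q) {
  Ak <- A; P <- Q
  for (i in 1:120) {
    Pn <- Ak %*% P %*% t(Ak) + P
    if (max(abs(Pn - P)) <= 1e-14 * max(abs(Pn), 1e-300)) return(Pn)
    P <- Pn
    Ak <- Ak %*% Ak
  }
  P
}

#' Stationary output spectra of a noise-driven discrete system
#'
#' For a discrete system driven by independent white input sequences with
#' standard deviations `input_sd`, returns the one-sided power per 1 Hz bin of
#' the (single) output on the given frequency grid. This is the analytic
#' counterpart of a Welch estimate with 1 Hz bins.
#'
#' @param sys a discrete-time `lti_ss` with one output.
#' @param input_sd per-channel white-noise standard deviations (length =
#'   number of inputs).
#' @param f frequency grid in Hz.
#' @return numeric vector of per-bin power.
#' @export
analytic_output_psd <- function(sys, input_sd, f) {
  stopifnot(is_state_space(sys), sys$domain == "discrete",
            length(input_sd) == ncol(sys$B))
  fs <- 1 / sys$dt
  total <- rep(0, length(f))
  for (j in seq_along(input_sd)) {
    if (input_sd[j] == 0) next
    H <- frequency_response(sys, f, input = j)
    # white sequence of variance sd^2: two-sided density sd^2 / fs per Hz;
    # one-sided 1 Hz bins carry 2 sd^2 / fs except at DC and Nyquist
    dens <- input_sd[j]^2 / fs * Mod(H)^2
    w <- ifelse(f == 0 | abs(f - fs / 2) < 1e-9, 1, 2)
    total <- total + w * dens
  }
  total
}

#' Transfer function of a single channel of a state-space system
#'
#' Exact SISO transfer function `C (xI - A)^-1 B + D` for the selected input
#' channel, via the Leverrier-Faddeev recursion (characteristic polynomial
#' and adjugate expansion). Works in either domain.
#'
#' @param sys an `lti_ss` with one output.
#' @param input input channel index.
#' @return an `lti_tf` in the matching domain.
#' @export
ss_to_tf <- function(sys, input = 1L) {
  stopifnot(is_state_space(sys), nrow(sys$C) == 1L)
  A <- sys$A; n <- nrow(A)
  B <- sys$B[, input, drop = FALSE]
  C <- sys$C; D <- sys$D[1L, input]
  dom <- if (sys$domain == "continuous") "s" else "z"
  if (n == 0L) return(transfer_function(D, 1, dom, sys$dt))
  den <- numeric(n + 1L); den[1L] <- 1
  Rk <- diag(1, n)
  num <- numeric(n)
  for (k in seq_len(n)) {
    num[k] <- (C %*% Rk %*% B)[1L]
    Ak <- A %*% Rk
    den[k + 1L] <- -sum(diag(Ak)) / k
    Rk <- Ak + den[k + 1L] * diag(1, n)
  }
  transfer_function(poly_add(num, D * den), den, dom, sys$dt)
}

#' Discretization of a transfer function
#'
#' `method = "zoh"` realizes the continuous transfer function in state space,
#' discretizes by zero-order hold and converts back; the physically correct
#' choice for plants whose inputs are sample-and-hold signals. `method =
#' "tustin"` applies the bilinear map `s = (2 / dt) (z - 1) / (z + 1)`, which
#' tracks the continuous frequency response much more closely over the control
#' band (no half-sample hold lag); used when deploying synthesized
#' controllers.
#'
#' @param tf a proper continuous-time `lti_tf`.
#' @param dt sampling time in seconds.
#' @param method `"zoh"` or `"tustin"`.
#' @return a discrete-time `lti_tf`.
#' @export
discretize_tf <- function(tf, dt, method = c("zoh", "tustin")) {
  method <- match.arg(method)
  stopifnot(is_transfer_function(tf), tf$domain == "s")
  if (method == "zoh")
    return(ss_to_tf(discretize(to_state_space(tf), dt)))
  # bilinear: substitute s -> (2/dt) (z-1)/(z+1) and clear (z+1)^n
  n <- max(length(tf$num), length(tf$den)) - 1L
  sub_poly <- function(p) {
    p <- c(rep(0, n + 1L - length(p)), p)   # pad to common degree
    acc <- rep(0, n + 1L)
    for (k in seq_along(p)) {
      deg_s <- length(p) - k                # power of s of this coefficient
      term <- p[k] * (2 / dt)^deg_s
      pol <- 1
      if (deg_s > 0) for (i in seq_len(deg_s)) pol <- poly_mul(pol, c(1, -1))
      if (n - deg_s > 0) for (i in seq_len(n - deg_s)) pol <- poly_mul(pol, c(1, 1))
      acc <- poly_add(acc, term * pol)
    }
    acc
  }
  transfer_function(sub_poly(tf$num), sub_poly(tf$den), "z", dt)
}
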