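#' Rational transfer functions
#'
#' `transfer_function()` constructs a rational transfer function in the Laplace
#' domain (`domain = "s"`, continuous time) or the z-domain (`domain = "z"`,
#' discrete time with sampling time `dt`). Coefficients are given in descending
#' powers, in the usual control-engineering order. The representation is
#' normalized to a monic denominator.
#'
#' @param num numeric vector of numerator coefficients, descending powers.
#' @param den numeric vector of denominator coefficients, descending powers;
#'   the leading coefficient must be nonzero.
#' @param domain `"s"` for continuous time, `"z"` for discrete time.
#' @param dt sampling time in seconds; required when `domain = "z"`.
#' @return an object of class `lti_tf`.
#' @examples
#' G <- transfer_function(1, c(1, 1))           # 1 / (s + 1)
#' frequency_response(G, c(0, 1, 10))
#' @export
transfer_function <- function(num, den, domain = c("s", "z"), dt = NULL) {
  domain <- match.arg(domain)
  num <- as.numeric(num)
  den <- as.numeric(den)
  stopifnot(length(den) >= 1L, length(num) >= 1L)
  num <- strip_leading_zeros(num)
  den <- strip_leading_zeros(den)
  if (abs(den[1L]) < .Machine$double.eps)
    stop("denominator leading coefficient is zero")
  if (domain == "z") {
    if (is.null(dt) || !is.finite(dt) || dt <= 0)
      stop("discrete-time transfer functions require a positive sampling time `dt`")
  } else {
    dt <- NULL
  }
  num <- num / den[1L]
  den <- den / den[1L]
  structure(list(num = num, den = den, domain = domain, dt = dt),
            class = "lti_tf")
}

strip_leading_zeros <- function(p) {
  nz <- which(abs(p) > 0)
  if (length(nz) == 0L) return(0)
  p[nz[1L]:length(p)]
}

#' @exportS3Method base::print
print.lti_tf <- function(x, ...) {
  var <- if (x$domain == "s") "s" else "z"
  cat("Rational transfer function (", if (x$domain == "s") "continuous" else
    sprintf("discrete, dt = %g s", x$dt), ")\n", sep = "")
  cat("  num:", format(signif(x$num, 6)), "\n")
  cat("  den:", format(signif(x$den, 6)), "\n")
  cat("  orders: ", length(x$num) - 1L, " / ", length(x$den) - 1L,
      " in ", var, "\n", sep = "")
  invisible(x)
}

#' @rdname transfer_function
#' @param x object to test.
#' @export
is_transfer_function <- function(x) inherits(x, "lti_tf")

tf_degree <- function(tf) c(num = length(tf$num) - 1L, den = length(tf$den) - 1L)

#' Properness of a transfer function
#'
#' A rational transfer function is proper when the numerator degree does not
#' exceed the denominator degree (required for a state-space realization), and
#' strictly proper when it is smaller.
#'
#' @param tf an `lti_tf`.
#' @param strictly require numerator degree strictly below denominator degree.
#' @return logical.
#' @export
is_proper <- function(tf, strictly = FALSE) {
  d <- tf_degree(tf)
  if (strictly) d["num"] < d["den"] else d["num"] <= d["den"]
}

#' Poles and zeros
#'
#' Roots of the denominator and numerator polynomials.
#'
#' @param tf an `lti_tf`.
#' @return complex vector.
#' @export
tf_poles <- function(tf) polynomial_roots(tf$den)

#' @rdname tf_poles
#' @export
tf_zeros <- function(tf) polynomial_roots(tf$num)

polynomial_roots <- function(p) {
  p <- strip_leading_zeros(p)
  if (length(p) <= 1L) return(complex(0))
  # polyroot takes ascending coefficients
  polyroot(rev(p))
}

polyval_desc <- function(p, x) {
  out <- rep_len(if (is.complex(x)) 0 + 0i else 0, length(x))
  for (coef in p) out <- out * x + coef
  out
}

poly_from_roots <- function(r, lead = 1) {
  p <- as.complex(lead)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

poly_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  if (is.complex(a) || is.complex(b)) out <- as.complex(out)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(rep(0, n - length(a)), a) + c(rep(0, n - length(b)), b)
}

check_same_domain <- function(a, b) {
  if (a$domain != b$domain)
    stop("cannot combine continuous- and discrete-time transfer functions")
  if (a$domain == "z" && !isTRUE(all.equal(a$dt, b$dt)))
    stop("sampling times differ")
}

#' @export
Ops.lti_tf <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(transfer_function(-e1$num, e1$den, e1$domain, e1$dt))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operator for lti_tf: ", .Generic)
  }
  if (!is_transfer_function(e1)) e1 <- tf_constant(e1, e2)
  if (!is_transfer_function(e2)) e2 <- tf_constant(e2, e1)
  check_same_domain(e1, e2)
  dom <- e1$domain; dt <- e1$dt
  switch(.Generic,
    "+" = transfer_function(poly_add(poly_mul(e1$num, e2$den), poly_mul(e2$num, e1$den)),
                            poly_mul(e1$den, e2$den), dom, dt),
    "-" = transfer_function(poly_add(poly_mul(e1$num, e2$den), -poly_mul(e2$num, e1$den)),
                            poly_mul(e1$den, e2$den), dom, dt),
    "*" = transfer_function(poly_mul(e1$num, e2$num), poly_mul(e1$den, e2$den), dom, dt),
    "/" = {
      if (all(abs(e2$num) < .Machine$double.eps)) stop("division by the zero system")
      transfer_function(poly_mul(e1$num, e2$den), poly_mul(e1$den, e2$num), dom, dt)
    },
    stop("unsupported operator for lti_tf: ", .Generic)
  )
}

tf_constant <- function(value, like) {
  stopifnot(is.numeric(value), length(value) == 1L)
  transfer_function(value, 1, like$domain, like$dt)
}

#' Frequency response of an LTI system
#'
#' Evaluates the transfer function at `s = 2 * pi * 1i * f` (continuous) or
#' `z = exp(2 * pi * 1i * f * dt)` (discrete). For state-space systems the
#' response `C (sI - A)^-1 B + D` is computed by a dense linear solve per
#' frequency. Evaluation at (or numerically near) a pole yields a non-finite
#' value rather than an error.
#'
#' @param sys an `lti_tf` or `lti_ss` (single-input single-output for `lti_ss`
#'   unless `input`/`output` select a channel).
#' @param f numeric vector of frequencies in Hz (nonnegative; at most the
#'   Nyquist frequency for discrete-time systems).
#' @param ... passed to methods.
#' @return complex vector, one value per frequency.
#' @export
frequency_response <- function(sys, f, ...) UseMethod("frequency_response")

#' @export
frequency_response.lti_tf <- function(sys, f, ...) {
  stopifnot(all(f >= 0))
  x <- tf_eval_points(sys, f)
  polyval_desc(sys$num, x) / polyval_desc(sys$den, x)
}

tf_eval_points <- function(sys, f) {
  if (sys$domain == "s") {
    2i * pi * f
  } else {
    if (any(f > 1 / (2 * sys$dt) + 1e-9))
      stop("frequencies above the Nyquist frequency ", 1 / (2 * sys$dt), " Hz")
    exp(2i * pi * f * sys$dt)
  }
}

#' Group delay of a discrete-time transfer function
#'
#' Numerical derivative of the phase response, `-d arg(G) / d omega`, in
#' seconds. Negative values mean the system anticipates its input in the
#' corresponding band (negative group delay).
#'
#' @param tf a discrete-time `lti_tf`.
#' @param f frequencies in Hz.
#' @param df finite-difference step in Hz.
#' @return numeric vector of group delays (seconds).
#' @export
group_delay <- function(tf, f, df = 1e-3) {
  stopifnot(tf$domain == "z")
  h1 <- frequency_response(tf, pmax(f - df / 2, 0))
  h2 <- frequency_response(tf, f + df / 2)
  -Arg(h2 / h1) / (2 * pi * df)
}

#' Minimal form of a transfer function
#'
#' Cancels numerator/denominator root pairs closer than a relative tolerance
#' (exact pole-zero cancellations survive the polynomial arithmetic of
#' composite expressions such as controller synthesis and would otherwise
#' linger as spurious marginal modes in realizations).
#'
#' @param tf an `lti_tf`.
#' @param tol relative cancellation tolerance.
#' @return an `lti_tf` with common factors removed.
#' @export
tf_minreal <- function(tf, tol = 1e-7) {
  z <- polynomial_roots(tf$num)
  p <- polynomial_roots(tf$den)
  gain_num <- tf$num[1L]   # den is monic
  scale <- max(Mod(c(z, p)), 1)
  keep_z <- rep(TRUE, length(z)); keep_p <- rep(TRUE, length(p))
  for (i in seq_along(z)) {
    j <- which(keep_p & Mod(p - z[i]) < tol * scale)
    if (length(j) > 0L) { keep_z[i] <- FALSE; keep_p[j[1L]] <- FALSE }
  }
  if (all(keep_z) && all(keep_p)) return(tf)
  transfer_function(Re(poly_from_roots(z[keep_z], gain_num)),
                    Re(poly_from_roots(p[keep_p])), tf$domain, tf$dt)
}
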