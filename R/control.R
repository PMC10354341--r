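#' Band specification of the target filter
#'
#' One band of the band-shaping filter: a unit-peak second-order bandpass
#' `c * 2 pi B s / (s^2 + 2 pi B s + (2 pi f)^2)` whose response at the
#' natural frequency `f` is exactly the weight `c`. Positive weights boost
#' the band, negative weights (in `(-1, 0)`) suppress it.
#'
#' @param f natural frequency in Hz (> 0).
#' @param B bandwidth in Hz (> 0).
#' @param c signed weight.
#' @return a list of class `filter_band`.
#' @export
filter_band <- function(f, B, c) {
  stopifnot(f > 0, B > 0, is.finite(c))
  structure(list(f = f, B = B, c = c), class = "filter_band")
}

#' Default alpha/gamma band-shaping specification
#'
#' The psychosis-motivated default: boost the alpha band (10 Hz natural
#' frequency, 4 Hz width, weight +1.0) and suppress the gamma band (40 Hz,
#' 30 Hz width, weight -0.5).
#'
#' @return list of two [filter_band()] objects.
#' @export
default_filter_bands <- function() {
  list(filter_band(10, 4, 1.0), filter_band(40, 30, -0.5))
}

#' Build the band-shaping target filter H
#'
#' Sum of unit-peak second-order bandpass terms, one per band. The result
#' vanishes at DC and at infinite frequency, so the closed loop leaves the
#' very low and very high frequency content of the resting activity
#' untouched.
#'
#' @param bands list of [filter_band()] objects (empty list gives `H = 0`).
#' @return an `lti_tf` in the Laplace domain.
#' @export
build_filter <- function(bands = default_filter_bands()) {
  if (inherits(bands, "filter_band")) bands <- list(bands)
  H <- transfer_function(0, 1, domain = "s")
  for (bd in bands) {
    stopifnot(inherits(bd, "filter_band"))
    term <- transfer_function(c(bd$c * 2 * pi * bd$B, 0),
                              c(1, 2 * pi * bd$B, (2 * pi * bd$f)^2),
                              domain = "s")
    H <- H + term
  }
  H
}

#' Closed-loop transfer function
#'
#' The sensitivity-type map from the resting activity to the closed-loop
#' output, `1 / (1 - G K)`, for a plant `G` in positive feedback with the
#' controller `K`. Stability is reported via the pole check; an imaginary-axis
#' pole-zero cancellation is flagged with a warning.
#'
#' @param G plant transfer function (`lti_tf`).
#' @param K controller transfer function (`lti_tf`).
#' @return an `lti_tf` with attribute `"stable"`.
#' @export
closed_loop_response <- function(G, K) {
  stopifnot(is_transfer_function(G), is_transfer_function(K))
  L <- G * K
  one <- tf_constant(1, L)
  S <- one / (one - L)
  p <- tf_poles(S)
  axis <- if (S$domain == "s") abs(Re(p)) < 1e-7 * pmax(Mod(p), 1)
          else abs(Mod(p) - 1) < 1e-7
  if (any(axis)) {
    z <- tf_zeros(S)
    if (any(vapply(p[axis], function(pp) any(Mod(z - pp) < 1e-6 * max(Mod(pp), 1)), TRUE)))
      warning("pole-zero cancellation on the stability boundary")
  }
  stable <- if (S$domain == "s") all(Re(p) < 0) else all(Mod(p) < 1)
  attr(S, "stable") <- stable
  S
}

#' Synthesize the spectrum-shaping controller
#'
#' Solves the closed-loop design identity `1 / (1 - G K) = 1 + H` for the
#' controller, `K = H / ((1 + H) G)`. When the resulting rational function is
#' improper (the plant rolls off faster than the filter), first-order
#' low-pass factors `1 / (s / (2 pi f_c) + 1)` are appended until the
#' controller is proper so it can be realized in state space; with the
#' default corner at 300 Hz the distortion below 100 Hz is negligible.
#'
#' @param H target filter (`lti_tf`), e.g. from [build_filter()].
#' @param G plant input-response model (`lti_tf`), exact or fitted. Must be
#'   minimum phase (no right-half-plane zeros): the synthesis inverts `G`.
#' @param f_c corner frequency in Hz of the regularizing low-pass factors.
#' @return an `lti_tf` with attribute `"n_lowpass"` (number of appended
#'   factors).
#' @export
synthesize_controller <- function(H, G, f_c = 300) {
  stopifnot(is_transfer_function(H), is_transfer_function(G),
            H$domain == "s", G$domain == "s")
  gz <- tf_zeros(G)
  if (any(Re(gz) > 1e-7 * pmax(Mod(gz), 1)))
    stop("plant model has right-half-plane zeros; inverting it would give an ",
         "unstable controller")
  one <- tf_constant(1, H)
  K <- tf_minreal(H / ((one + H) * G))
  deg <- tf_degree(K)
  n_lp <- max(0L, deg["num"] - deg["den"])
  if (n_lp > 0L) {
    lp <- transfer_function(1, c(1 / (2 * pi * f_c), 1), domain = "s")
    for (i in seq_len(n_lp)) K <- K * lp
  }
  attr(K, "n_lowpass") <- as.integer(n_lp)
  K
}
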