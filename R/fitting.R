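#' Configuration for magnitude-only vector fitting
#'
#' @param n_poles model order of the fitted transfer function (number of
#'   stable poles, >= 2; initial resonances are placed in conjugate pairs).
#' @param n_iterations maximum pole-relocation iterations.
#' @param initial_pole_spread `[f_lo, f_hi]` in Hz over which starting
#'   resonance frequencies are log-spaced.
#' @param enforce_stability keep all fitted poles strictly in the left half
#'   plane (reflection plus a small damping floor).
#' @param allow_feedthrough allow a nonzero direct-transmission term, i.e. a
#'   proper (rather than strictly proper) fitted model. Used to identify and
#'   remove direct input-current measurement artifacts.
#' @param dc_zero impose a structural transmission zero at `s = 0` (default
#'   `TRUE`): EEG/LFP observation chains are AC-coupled, so the physical
#'   plant input response vanishes at DC. The squared-magnitude data is
#'   fitted as `omega^2` times a rational remainder, which anchors the
#'   low-frequency behavior where the spectral-subtraction data is noise
#'   dominated. Incompatible with `allow_feedthrough`.
#' @param weighting least-squares weighting of the magnitude-squared rows:
#'   `"inverse_variance"` (default; weight `1/noise_sd` using the per-bin
#'   estimation noise attached by [extract_gain()], falling back to
#'   `"amplitude"` when absent), `"amplitude"` (weight `1/sqrt(d)`, i.e.
#'   mean square error on the magnitude samples), `"uniform"` (mean square
#'   error on the squared magnitude), or `"relative"` (weight `1/d`).
#' @param pole_tol relative pole-movement threshold declaring convergence.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(n_poles = 4L, n_iterations = 20L,
                       initial_pole_spread = c(1, 100),
                       enforce_stability = TRUE,
                       allow_feedthrough = FALSE,
                       dc_zero = TRUE,
                       weighting = c("inverse_variance", "amplitude",
                                     "uniform", "relative"),
                       pole_tol = 1e-6) {
  weighting <- match.arg(weighting)
  if (isTRUE(dc_zero) && isTRUE(allow_feedthrough))
    stop("dc_zero and allow_feedthrough are mutually exclusive")
  stopifnot(n_poles >= 2L, n_iterations >= 1L,
            length(initial_pole_spread) == 2L,
            initial_pole_spread[1] > 0,
            initial_pole_spread[2] > initial_pole_spread[1])
  structure(list(n_poles = as.integer(n_poles),
                 n_iterations = as.integer(n_iterations),
                 initial_pole_spread = as.numeric(initial_pole_spread),
                 enforce_stability = isTRUE(enforce_stability),
                 allow_feedthrough = isTRUE(allow_feedthrough),
                 dc_zero = isTRUE(dc_zero),
                 weighting = weighting,
                 pole_tol = pole_tol),
            class = "fit_config")
}

#' Magnitude-only vector fitting of a stable transfer function
#'
#' Fits a stable, minimum-phase, real-rational continuous-time transfer
#' function to squared-magnitude samples `|g(f)|^2`, using only magnitude
#' information. Because `|G(i omega)|^2 = G(s) G(-s)` on the imaginary axis
#' is a real rational function of `X = omega^2`, the algorithm (i) runs
#' iterative vector fitting with relocated conjugate-pair poles on the
#' magnitude-squared data in the variable `X`, and (ii) recovers the stable
#' minimum-phase spectral factor by splitting the roots of the fitted
#' numerator and denominator of `R(-s^2)` between the left and right half
#' planes. The overall gain is refit by least squares and taken positive, so
#' the result also reproduces the phase of minimum-phase targets with
#' positive static gain.
#'
#' @param data a [gain_samples()] object (`|g|^2` versus frequency in Hz).
#' @param config a [fit_config()].
#' @return an `lti_tf` (continuous time) with attribute `"fit"`: a list with
#'   `converged`, `iterations`, `residual` (mean squared magnitude-squared
#'   error), and `n_poles`. Non-convergence is flagged, not an error.
#' @export
magnitude_vector_fit <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "gain_samples"), inherits(config, "fit_config"))
  f <- data$frequencies
  d <- data$magnitude_squared
  m <- config$n_poles
  if (length(f) < 4L * m)
    stop("need at least ", 4L * m, " data points for ", m, " poles; got ",
         length(f))
  w_s <- 2 * pi * max(f)
  X <- (2 * pi * f / w_s)^2
  if (config$dc_zero && any(f <= 0))
    stop("dc_zero fitting requires strictly positive frequencies")
  draw <- d
  dscale_raw <- max(draw)
  if (dscale_raw <= 0) stop("all-zero magnitude data")
  # weights are always formed in the original |g|^2 space
  dnr <- draw / dscale_raw
  wfloor <- stats::quantile(dnr[dnr > 0], 0.05)
  weighting <- config$weighting
  if (weighting == "inverse_variance" && is.null(data$noise_sd))
    weighting <- "amplitude"
  wts <- switch(weighting,
    inverse_variance = {
      w <- 1 / (data$noise_sd / dscale_raw)
      w / max(w)
    },
    uniform = rep(1, length(dnr)),
    amplitude = 1 / sqrt(pmax(dnr, wfloor)),
    relative = 1 / pmax(dnr, wfloor))
  if (config$dc_zero) {
    d <- d / X
    wts <- wts * X
    wts <- wts / max(wts)
  }
  dscale <- max(d)
  dn <- d / dscale

  # two starts: resonances at the strongest spectral peaks of the data, and a
  # log-spaced ladder over the pole spread; relocation then refines either
  n_pairs <- ceiling(m / 2)
  starts <- list(vf_init_peaks(f, dnr, n_pairs, config$initial_pole_spread, w_s),
                 vf_init_ladder(f, n_pairs, config$initial_pole_spread, w_s))
  best <- NULL
  converged <- FALSE
  iterations <- 0L
  for (start in starts) {
    poles <- start[seq_len(min(m, length(start)))]
    run_conv <- FALSE
    pole_history <- list(poles)
    for (it in seq_len(config$n_iterations)) {
      iterations <- max(iterations, it)
      sol <- tryCatch(
        vf_ls_solve(X, dn, poles, config$allow_feedthrough, relocate = TRUE,
                    weights = wts, residue_sum_zero = config$dc_zero),
        error = function(e) NULL)
      if (is.null(sol)) break
      new_poles <- vf_sigma_zeros(poles, sol$sigma_res)
      move <- vf_pole_distance(poles, new_poles)
      poles <- new_poles
      pole_history[[length(pole_history) + 1L]] <- poles
      if (move < config$pole_tol) { run_conv <- TRUE; break }
    }
    # pole relocation can oscillate or settle on a poor local optimum under
    # estimation noise: keep the pole set (over all starts and iterations)
    # whose residue-only refit has the smallest weighted residual
    for (ps in pole_history) {
      cand <- tryCatch(
        vf_ls_solve(X, dn, ps, config$allow_feedthrough, relocate = FALSE,
                    weights = wts, residue_sum_zero = config$dc_zero),
        error = function(e) NULL)
      if (is.null(cand)) next
      rss <- vf_model_rss(X, dn, cand, wts)
      if (is.null(best) || rss < best$rss) {
        best <- list(sol = cand, poles = ps, rss = rss)
        converged <- run_conv
      }
    }
  }
  if (is.null(best)) stop("vector fitting failed at every pole set")
  poles <- best$poles
  final <- best$sol

  tf <- vf_spectral_factor(poles, final$residues, final$feedthrough,
                           X, dn, w_s, dscale, config$enforce_stability,
                           weights = wts)
  if (config$dc_zero)
    tf <- transfer_function(c(tf$num, 0) / w_s, tf$den, domain = "s")
  resp <- Mod(frequency_response(tf, f))^2
  attr(tf, "fit") <- list(converged = converged, iterations = iterations,
                          residual = mean((resp - d)^2),
                          relative_residual = sqrt(mean((resp - d)^2)) / dscale,
                          n_poles = m)
  tf
}

# Initial X-domain poles: conjugate pairs with damping ratio ~0.25 at given
# resonance frequencies (Hz).
vf_pairs_at <- function(f0, w_s) {
  base <- (2 * pi * f0 / w_s)^2
  p <- as.complex(rbind(base * complex(real = 1, imaginary = 0.5),
                        base * complex(real = 1, imaginary = -0.5)))
  as.complex(p)
}

vf_init_ladder <- function(f, n_pairs, spread, w_s) {
  f0 <- exp(seq(log(max(spread[1], min(f[f > 0]))),
                log(min(spread[2], max(f))),
                length.out = n_pairs))
  vf_pairs_at(f0, w_s)
}

# Place initial resonances at the n_pairs largest local maxima of the
# (lightly smoothed) data; fall back to ladder positions for missing peaks.
vf_init_peaks <- function(f, d, n_pairs, spread, w_s) {
  k <- min(5L, length(d))
  sm <- stats::filter(d, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- d[is.na(sm)]
  n <- length(sm)
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n],
               FALSE)
  pk <- order(sm * is_peak, decreasing = TRUE)
  pk <- pk[sm[pk] > 0 & is_peak[pk]]
  f0 <- f[utils::head(pk, n_pairs)]
  if (length(f0) < n_pairs) {
    extra <- vf_init_ladder(f, n_pairs, spread, w_s)
    return(c(vf_pairs_at(f0, w_s), extra)[seq_len(2 * n_pairs)])
  }
  vf_pairs_at(sort(f0), w_s)
}

# Real-basis vector-fitting least squares at fixed poles. Complex poles are
# assumed conjugate-closed; each conjugate pair contributes the real basis
# 2 Re 1/(X - p), -2 Im 1/(X - p); real poles contribute 1/(X - p).
vf_basis <- function(X, poles) {
  info <- vf_pole_groups(poles)
  cols <- list()
  for (g in info) {
    cp <- 1 / (X - g$pole)
    if (g$real) cols[[length(cols) + 1L]] <- Re(cp)
    else {
      cols[[length(cols) + 1L]] <- 2 * Re(cp)
      cols[[length(cols) + 1L]] <- -2 * Im(cp)
    }
  }
  do.call(cbind, cols)
}

vf_pole_groups <- function(poles) {
  used <- rep(FALSE, length(poles))
  out <- list()
  for (i in seq_along(poles)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) < 1e-12 * max(abs(p), 1)) {
      out[[length(out) + 1L]] <- list(pole = complex(real = Re(p)), real = TRUE)
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(poles - Conj(p)) < 1e-8 * max(abs(p), 1))
      j <- setdiff(j, i)
      if (length(j) == 0L) stop("poles are not conjugate-closed")
      used[c(i, j[1L])] <- TRUE
      if (Im(p) < 0) p <- Conj(p)
      out[[length(out) + 1L]] <- list(pole = p, real = FALSE)
    }
  }
  out
}

vf_ls_solve <- function(X, d, poles, allow_feedthrough, relocate,
                        weights = NULL, residue_sum_zero = FALSE) {
  Phi <- vf_basis(X, poles)
  Amat <- Phi
  if (allow_feedthrough) Amat <- cbind(Amat, 1)
  if (relocate) Amat <- cbind(Amat, -d * Phi)
  rhs <- d
  if (!is.null(weights)) { Amat <- Amat * weights; rhs <- d * weights }
  nb <- ncol(Phi)
  Nbasis <- NULL
  if (residue_sum_zero) {
    # restrict the residue block to the null space of the residue-sum
    # functional: drops the numerator degree by one so the reassembled model
    # stays strictly proper after the extra structural zero
    row <- vf_residue_sum_row(poles)
    Nbasis <- qr.Q(qr(cbind(row)), complete = TRUE)[, -1L, drop = FALSE]
    Amat <- cbind(Amat[, seq_len(nb), drop = FALSE] %*% Nbasis,
                  Amat[, -seq_len(nb), drop = FALSE])
  }
  fit <- svd_lstsq(Amat, rhs)
  if (is.null(fit))
    stop("rank-deficient least squares in vector fitting; supply more data ",
         "points or reduce n_poles")
  nres <- if (residue_sum_zero) nb - 1L else nb
  res_coef <- fit[seq_len(nres)]
  if (residue_sum_zero) res_coef <- drop(Nbasis %*% res_coef)
  feed <- if (allow_feedthrough) fit[nres + 1L] else 0
  sigma_coef <- if (relocate) fit[(length(fit) - nb + 1L):length(fit)] else NULL
  list(residues = vf_coef_to_residues(poles, res_coef),
       feedthrough = feed,
       sigma_res = if (relocate) vf_coef_to_residues(poles, sigma_coef) else NULL)
}

# Coefficients of sum(residues) in the real residue basis: 2 per conjugate
# pair's real part, 1 per real pole.
vf_residue_sum_row <- function(poles) {
  info <- vf_pole_groups(poles)
  unlist(lapply(info, function(g) if (g$real) 1 else c(2, 0)))
}

# Weighted residual sum of squares of the pole-residue model against data.
vf_model_rss <- function(X, d, sol, wts) {
  r <- vf_eval_pr(X, sol$residues, sol$feedthrough) - d
  sum((r * wts)^2)
}

# Evaluate sum r_i / (X - p_i) + e over the conjugate-expanded residue set.
vf_eval_pr <- function(X, res, feed) {
  out <- rep(feed, length(X))
  for (i in seq_along(res$poles)) {
    term <- res$residues[i] / (X - res$poles[i])
    out <- out + if (res$real[i]) Re(term) else 2 * Re(term)
  }
  out
}

# Minimum-norm least squares via SVD with relative tolerance; returns NULL
# only when the design matrix is numerically zero.
svd_lstsq <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d)
  if (!any(keep)) return(NULL)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep]))
}

# Map the real basis coefficients back to complex residues aligned with
# vf_pole_groups(); returns list(poles = representative poles, residues).
vf_coef_to_residues <- function(poles, coef) {
  info <- vf_pole_groups(poles)
  res <- complex(length(info)); reps <- complex(length(info))
  k <- 1L
  for (i in seq_along(info)) {
    reps[i] <- info[[i]]$pole
    if (info[[i]]$real) {
      res[i] <- coef[k]; k <- k + 1L
    } else {
      res[i] <- complex(real = coef[k], imaginary = coef[k + 1L])
      k <- k + 2L
    }
  }
  list(poles = reps, residues = res, real = vapply(info, `[[`, TRUE, "real"))
}

# Zeros of sigma(X) = 1 + sum c_i / (X - a_i): eigenvalues of diag(a) - 1 c^T
# over the full conjugate-expanded pole/residue set.
vf_sigma_zeros <- function(poles, sig) {
  a <- c(); cc <- c()
  for (i in seq_along(sig$poles)) {
    if (sig$real[i]) {
      a <- c(a, sig$poles[i]); cc <- c(cc, sig$residues[i])
    } else {
      a <- c(a, sig$poles[i], Conj(sig$poles[i]))
      cc <- c(cc, sig$residues[i], Conj(sig$residues[i]))
    }
  }
  M <- diag(a, length(a)) - matrix(1, length(a), 1) %*% matrix(cc, 1)
  z <- eigen(M, only.values = TRUE)$values
  # force conjugate closure against numerical asymmetry
  z[abs(Im(z)) < 1e-10 * pmax(abs(z), 1)] <- complex(real = Re(z[abs(Im(z)) < 1e-10 * pmax(abs(z), 1)]))
  z
}

vf_pole_distance <- function(p, q) {
  if (length(p) != length(q)) return(Inf)
  ps <- p[order(Re(p), Im(p))]; qs <- q[order(Re(q), Im(q))]
  max(abs(ps - qs) / pmax(abs(ps), 1e-12))
}

# Build the stable minimum-phase spectral factor from the fitted rational
# approximation R(X) = sum r_i/(X - p_i) + e of |G|^2 in X = (omega/w_s)^2.
vf_spectral_factor <- function(poles, res, feed, X, dn, w_s, dscale,
                               enforce_stability, weights = NULL) {
  # expand to full conjugate sets
  a <- c(); r <- c()
  for (i in seq_along(res$poles)) {
    if (res$real[i]) { a <- c(a, res$poles[i]); r <- c(r, res$residues[i]) }
    else {
      a <- c(a, res$poles[i], Conj(res$poles[i]))
      r <- c(r, res$residues[i], Conj(res$residues[i]))
    }
  }
  m <- length(a)
  DX <- poly_from_roots(a)                       # monic, complex -> real
  NX <- rep(0 + 0i, 1L)
  for (i in seq_len(m)) {
    others <- poly_from_roots(a[-i])
    NX <- poly_add(NX, r[i] * others)
  }
  if (abs(feed) > 0) NX <- poly_add(NX, feed * DX)
  DX <- Re(DX); NX <- Re(NX)
  # drop numerically vanished leading coefficients (e.g. from the
  # residue-sum-zero constraint) before rooting
  while (length(NX) > 1L && abs(NX[1L]) < 1e-9 * max(abs(NX)))
    NX <- NX[-1L]

  # stable half of the denominator: X-pole p -> s' with s'^2 = -p, Re < 0
  sp <- vapply(a, function(p) half_root(-p, enforce_stability), complex(1))
  # minimum-phase half of the numerator
  zX <- polynomial_roots(NX)
  sz <- vapply(zX, function(q) half_root(-q, FALSE), complex(1))

  den_s <- Re(poly_from_roots(reflect_lhp(sp * w_s, enforce_stability)))
  num_s <- Re(poly_from_roots(reflect_lhp(sz * w_s, FALSE)))
  # taking real parts of near-conjugate products can nudge roots across the
  # axis; reflect the realized roots once more
  den_s <- Re(poly_from_roots(reflect_lhp(polynomial_roots(den_s), enforce_stability)))
  num_s <- Re(poly_from_roots(reflect_lhp(polynomial_roots(num_s), FALSE)))
  G1 <- transfer_function(num_s, den_s, domain = "s")

  # least-squares positive gain on the original grid
  f_grid <- sqrt(X) * w_s / (2 * pi)
  h2 <- Mod(frequency_response(G1, f_grid))^2
  w2 <- if (is.null(weights)) rep(1, length(dn)) else weights^2
  g2 <- sum(w2 * h2 * dn) / sum(w2 * h2^2)
  if (!is.finite(g2) || g2 <= 0) g2 <- max(dn) / max(h2)
  transfer_function(G1$num * sqrt(g2 * dscale), G1$den, domain = "s")
}

# Mirror right-half-plane roots into the left half plane; |.| on the
# imaginary axis is invariant under the reflection. A small damping floor is
# applied to axis poles when requested.
reflect_lhp <- function(r, damp_floor) {
  re <- -abs(Re(r))
  if (damp_floor) {
    axis <- abs(re) < 1e-9 * pmax(Mod(r), 1e-12)
    re[axis] <- -1e-6 * pmax(Mod(r[axis]), 1e-6)
  }
  complex(real = re, imaginary = Im(r))
}

# one root s of s^2 = v with Re(s) < 0 (or minimum-phase tie-break on the axis)
half_root <- function(v, damp_floor) {
  s <- sqrt(v)
  if (Re(s) > 0) s <- -s
  if (abs(Re(s)) < 1e-9 * max(abs(s), 1e-12)) {
    if (damp_floor) s <- complex(real = -1e-6 * max(abs(s), 1e-6), imaginary = Im(s))
  }
  s
}

#' Relative complex RMSE between two transfer functions
#'
#' Root of the mean squared relative complex deviation,
#' `sqrt(mean(|(G_fit - G_ref) / G_ref|^2)) * 100`, evaluated on the
#' frequency grid used for fitting. Both magnitude and phase errors are
#' penalized. Grid points where the reference vanishes are excluded with a
#' warning.
#'
#' @param fitted,reference `lti_tf` objects (or anything accepted by
#'   [frequency_response()]).
#' @param frequencies frequency grid in Hz.
#' @return RMSE in percent.
#' @export
relative_rmse <- function(fitted, reference, frequencies) {
  gf <- frequency_response(fitted, frequencies)
  gr <- frequency_response(reference, frequencies)
  ok <- is.finite(gr) & Mod(gr) > 0
  if (!all(ok)) {
    warning(sum(!ok), " grid points excluded: reference is zero or non-finite")
    gf <- gf[ok]; gr <- gr[ok]
  }
  100 * sqrt(mean(Mod((gf - gr) / gr)^2))
}

#' Write a fit report to JSON
#'
#' Serializes a fitted model from [magnitude_vector_fit()] with its poles,
#' zeros, coefficients, residual diagnostics and convergence flag; the
#' reference RMSE is included when supplied.
#'
#' @param fit an `lti_tf` returned by [magnitude_vector_fit()].
#' @param path output file path.
#' @param rmse_vs_reference optional RMSE (%) against a reference model.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, rmse_vs_reference = NULL) {
  info <- attr(fit, "fit")
  p <- tf_poles(fit); z <- tf_zeros(fit)
  obj <- list(num = fit$num, den = fit$den,
              poles = data.frame(re = Re(p), im = Im(p)),
              zeros = data.frame(re = Re(z), im = Im(z)),
              residual = info$residual,
              relative_residual = info$relative_residual,
              converged = info$converged,
              iterations = info$iterations,
              n_poles = info$n_poles,
              rmse_vs_reference = rmse_vs_reference)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
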