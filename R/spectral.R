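#' Power spectral density series
#'
#' Frequency bins (bin centers, Hz) with power per bin. Produced by
#' [welch_psd()] or [analytic_output_psd()] wrapped through [psd_series()].
#'
#' @param frequencies strictly increasing bin centers in Hz, first >= 0.
#' @param values nonnegative power per bin.
#' @param n_segments number of averaged segments (0 when analytic).
#' @return an object of class `psd_series`.
#' @export
psd_series <- function(frequencies, values, n_segments = 0L) {
  frequencies <- as.numeric(frequencies); values <- as.numeric(values)
  stopifnot(length(frequencies) == length(values),
            all(diff(frequencies) > 0), frequencies[1L] >= 0,
            all(values >= 0))
  structure(list(frequencies = frequencies, values = values,
                 n_segments = as.integer(n_segments)),
            class = "psd_series")
}

#' @exportS3Method base::print
print.psd_series <- function(x, ...) {
  cat(sprintf("PSD series: %d bins, %g-%g Hz%s\n", length(x$frequencies),
              min(x$frequencies), max(x$frequencies),
              if (x$n_segments > 0) sprintf(" (Welch, %d segments)", x$n_segments) else ""))
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann window, segment length
#' `sampling_rate / bin_width` (1 s segments for the default 1 Hz bins) and
#' 50% overlap. Values are one-sided power per bin, so that the sum over all
#' bins approximates the signal variance (Parseval).
#'
#' @param x a [signal_trace()].
#' @param bin_width frequency resolution in Hz (default 1).
#' @param detrend subtract the segment mean before windowing.
#' @return a [psd_series()] with bins from 0 Hz to the Nyquist frequency.
#' @export
welch_psd <- function(x, bin_width = 1, detrend = TRUE) {
  stopifnot(is_signal_trace(x))
  fs <- x$sampling_rate
  nseg <- round(fs / bin_width)
  if (nseg < 2) stop("bin width too large for the sampling rate")
  step <- nseg %/% 2L
  n <- length(x$samples)
  if (n < 2L * nseg)
    stop("signal too short for Welch estimation: need at least ",
         2L * nseg, " samples (2 segments), got ", n)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann
  U <- sum(w^2)
  segs <- vapply(starts, function(s) {
    seg <- x$samples[s:(s + nseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    seg * w
  }, numeric(nseg))
  spec <- Mod(stats::mvfft(segs))^2 / (U * nseg)  # power per bin, two-sided
  pgram <- rowMeans(spec)
  half <- nseg %/% 2L
  freqs <- (0:half) * bin_width
  vals <- pgram[1:(half + 1L)]
  # fold negative frequencies into the one-sided estimate
  idx <- 2:(half + if (nseg %% 2L == 0L) 0L else 1L)
  vals[idx] <- 2 * vals[idx]
  psd_series(freqs, vals, n_segments = length(starts))
}

check_same_grid <- function(a, b) {
  if (length(a$frequencies) != length(b$frequencies) ||
      any(abs(a$frequencies - b$frequencies) > 1e-9))
    stop("PSD frequency grids differ")
}

#' Band activity
#'
#' Sum of the PSD bins whose centers fall inside `[f_lo, f_hi]`, both edges
#' inclusive. With the 1 Hz bin convention the alpha band 8-12 Hz spans five
#' bins and the gamma band 25-55 Hz spans thirty-one.
#'
#' @param psd a [psd_series()].
#' @param band numeric length-2, band edges in Hz.
#' @return scalar band power.
#' @export
band_activity <- function(psd, band) {
  stopifnot(inherits(psd, "psd_series"), length(band) == 2L, band[1] <= band[2])
  sel <- psd$frequencies >= band[1] - 1e-9 & psd$frequencies <= band[2] + 1e-9
  if (!any(sel)) stop("no PSD bins inside band [", band[1], ", ", band[2], "] Hz")
  sum(psd$values[sel])
}

#' Mean spectral amplitude
#'
#' Total amplitude-spectrum content from 0 Hz to the Nyquist frequency: the
#' sum over 1 Hz bins of the square root of the per-bin power. This is the
#' "mean amplitude" used for the amplitude ratio and for reporting the
#' stimulation-current amplitude.
#'
#' @param psd a [psd_series()].
#' @return scalar.
#' @export
mean_amplitude <- function(psd) {
  stopifnot(inherits(psd, "psd_series"))
  sum(sqrt(psd$values))
}

#' Amplitude ratio between stimulated and resting output
#'
#' Quantifies how strongly the stimulation response stands out of the resting
#' activity; the signal-to-noise knob of the model-estimation step. The
#' default (`type = "amplitude"`) is the ratio of the summed amplitude
#' spectra, `sum(sqrt(S_yy)) / sum(sqrt(S_y0y0))` over all bins; this is the
#' operational definition the reported values follow. `type = "power"` is the
#' ratio of total powers, and `type = "per_frequency"` averages the per-bin
#' power ratio across bins.
#'
#' @param psd_y PSD of the stimulated output.
#' @param psd_y0 PSD of the resting output, on the same frequency grid.
#' @param type which ratio to compute (see Details).
#' @return scalar amplitude ratio.
#' @export
amplitude_ratio <- function(psd_y, psd_y0,
                            type = c("amplitude", "power", "per_frequency")) {
  type <- match.arg(type)
  stopifnot(inherits(psd_y, "psd_series"), inherits(psd_y0, "psd_series"))
  check_same_grid(psd_y, psd_y0)
  if (sum(psd_y0$values) <= 0) stop("resting PSD has zero total power")
  switch(type,
    amplitude = sum(sqrt(psd_y$values)) / sum(sqrt(psd_y0$values)),
    power = sum(psd_y$values) / sum(psd_y0$values),
    per_frequency = {
      ok <- psd_y0$values > 0
      mean(psd_y$values[ok] / psd_y0$values[ok])
    })
}

#' Squared plant gain samples
#'
#' Frequency-domain samples of `|g(f)|^2`, the squared magnitude of the plant
#' input response, as extracted by [extract_gain()] and consumed by
#' [magnitude_vector_fit()].
#'
#' @param frequencies frequencies in Hz.
#' @param magnitude_squared nonnegative squared-magnitude samples.
#' @param n_floored number of bins floored to zero during extraction.
#' @param noise_sd optional per-bin estimation noise level of
#'   `magnitude_squared` (up to a common factor), used for inverse-variance
#'   weighting during fitting.
#' @return an object of class `gain_samples`.
#' @export
gain_samples <- function(frequencies, magnitude_squared, n_floored = 0L,
                         noise_sd = NULL) {
  frequencies <- as.numeric(frequencies)
  magnitude_squared <- as.numeric(magnitude_squared)
  stopifnot(length(frequencies) == length(magnitude_squared),
            all(diff(frequencies) > 0), all(magnitude_squared >= 0))
  if (!is.null(noise_sd)) {
    noise_sd <- as.numeric(noise_sd)
    stopifnot(length(noise_sd) == length(frequencies), all(noise_sd > 0))
  }
  structure(list(frequencies = frequencies,
                 magnitude_squared = magnitude_squared,
                 n_floored = as.integer(n_floored),
                 noise_sd = noise_sd),
            class = "gain_samples")
}

#' @exportS3Method base::print
print.gain_samples <- function(x, ...) {
  cat(sprintf("Gain samples: %d points, %g-%g Hz (%d floored to 0)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$n_floored))
  invisible(x)
}

#' Extract the squared plant gain from stimulated and resting spectra
#'
#' Implements the spectral-subtraction identity
#' `|g(f)|^2 = (S_yy(f) - S_y0y0(f)) / S_uu(f)`: the resting-state power is
#' subtracted from the stimulated-output power and normalized by the known
#' input power. Bins where estimation noise makes the difference negative are
#' floored at zero and counted in the `n_floored` diagnostic. Per-bin noise
#' levels of the extracted samples (proportional to
#' `sqrt(S_yy^2 + S_y0y0^2) / S_uu`) are attached for inverse-variance
#' weighting by the fitter.
#'
#' @param psd_y PSD of the output during stimulation.
#' @param psd_y0 PSD of the resting output.
#' @param psd_u PSD of the stimulation input; must be positive on `f_range`.
#' @param f_range frequency range `[f_lo, f_hi]` in Hz kept for fitting
#'   (default 1-100 Hz).
#' @return a [gain_samples()] object restricted to `f_range`.
#' @export
extract_gain <- function(psd_y, psd_y0, psd_u, f_range = c(1, 100)) {
  stopifnot(inherits(psd_y, "psd_series"), inherits(psd_y0, "psd_series"),
            inherits(psd_u, "psd_series"), length(f_range) == 2L)
  check_same_grid(psd_y, psd_y0)
  check_same_grid(psd_y, psd_u)
  sel <- psd_y$frequencies >= f_range[1] - 1e-9 &
         psd_y$frequencies <= f_range[2] + 1e-9
  if (!any(sel)) stop("empty frequency range")
  su <- psd_u$values[sel]
  if (any(su <= 0)) stop("input PSD is zero inside the extraction range")
  diffv <- psd_y$values[sel] - psd_y0$values[sel]
  floored <- sum(diffv < 0)
  # chi-squared spread of the averaged periodograms: sd of the difference is
  # proportional to sqrt(S_yy^2 + S_y0y0^2) per bin (common factors drop out
  # of the fitting weights)
  nsd <- sqrt(psd_y$values[sel]^2 + psd_y0$values[sel]^2) / su
  nsd[nsd <= 0] <- min(nsd[nsd > 0], 1)
  gain_samples(psd_y$frequencies[sel], pmax(diffv, 0) / su,
               n_floored = floored, noise_sd = nsd)
}
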