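#' Uniformly sampled time series
#'
#' Light container for a real, uniformly sampled signal.
#'
#' @param samples numeric vector of finite sample values.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param label short text label.
#' @return an object of class `signal_trace`.
#' @export
signal_trace <- function(samples, sampling_rate, label = "") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("signal contains non-finite samples")
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 label = as.character(label)),
            class = "signal_trace")
}

#' @rdname signal_trace
#' @param x object to test.
#' @export
is_signal_trace <- function(x) inherits(x, "signal_trace")

#' @exportS3Method base::print
print.signal_trace <- function(x, ...) {
  cat(sprintf("Signal trace%s: %d samples at %g Hz (%.3f s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Drop an initial transient from a trace
#'
#' @param x a `signal_trace`.
#' @param seconds duration to discard from the start.
#' @return a shorter `signal_trace`.
#' @export
trim_transient <- function(x, seconds = 1) {
  stopifnot(is_signal_trace(x))
  k <- round(seconds * x$sampling_rate)
  if (k >= length(x$samples)) stop("transient longer than the trace")
  signal_trace(x$samples[-seq_len(k)], x$sampling_rate, x$label)
}

#' Signal and PSD CSV input/output
#'
#' Traces are exchanged as CSV with header `time_s,value`; power spectral
#' densities as CSV with header `freq_hz,psd`; gain samples as
#' `freq_hz,mag_sq`.
#'
#' @param x a `signal_trace` (or `psd_series` / `gain_samples`).
#' @param path file path.
#' @name trace_io
#' @return readers return the parsed object; writers return `path` invisibly.
NULL

#' @rdname trace_io
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(is_signal_trace(x))
  t <- seq_along(x$samples) - 1
  utils::write.csv(data.frame(time_s = t / x$sampling_rate, value = x$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns time_s,value")
  dt <- diff(d$time_s)
  if (length(dt) < 1L || diff(range(dt)) > 1e-9 * mean(dt))
    stop("time column is not uniformly sampled")
  signal_trace(d$value, 1 / mean(dt), label = basename(path))
}

#' @rdname trace_io
#' @export
write_psd_csv <- function(x, path) {
  stopifnot(inherits(x, "psd_series"))
  utils::write.csv(data.frame(freq_hz = x$frequencies, psd = x$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_psd_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("freq_hz", "psd") %in% names(d)))
    stop("expected columns freq_hz,psd")
  psd_series(d$freq_hz, d$psd)
}

#' @rdname trace_io
#' @export
write_gain_csv <- function(x, path) {
  stopifnot(inherits(x, "gain_samples"))
  utils::write.csv(data.frame(freq_hz = x$frequencies, mag_sq = x$magnitude_squared),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_gain_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("freq_hz", "mag_sq") %in% names(d)))
    stop("expected columns freq_hz,mag_sq")
  gain_samples(d$freq_hz, d$mag_sq)
}

#' System JSON serialization
#'
#' Transfer functions serialize as `{domain, num, den[, dt]}`; state-space
#' systems as `{domain, A, B, C, D[, dt]}` with row-major matrices.
#'
#' @param sys an `lti_tf` or `lti_ss`.
#' @param path file path.
#' @return `read_system_json` returns the parsed system; the writer returns
#'   `path` invisibly.
#' @export
write_system_json <- function(sys, path) {
  obj <- if (is_transfer_function(sys)) {
    list(kind = "tf", domain = sys$domain, num = sys$num, den = sys$den,
         dt = sys$dt)
  } else if (is_state_space(sys)) {
    list(kind = "ss", domain = sys$domain,
         n = nrow(sys$A), m = ncol(sys$B), p = nrow(sys$C),
         A = as.vector(t(sys$A)), B = as.vector(t(sys$B)),
         C = as.vector(t(sys$C)), D = as.vector(t(sys$D)), dt = sys$dt)
  } else stop("not an LTI system")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_system_json
#' @export
read_system_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$kind, "tf")) {
    transfer_function(obj$num, obj$den, domain = obj$domain,
                      dt = if (is.null(obj$dt)) NULL else obj$dt)
  } else if (identical(obj$kind, "ss")) {
    state_space(matrix(obj$A, obj$n, obj$n, byrow = TRUE),
                matrix(obj$B, obj$n, obj$m, byrow = TRUE),
                matrix(obj$C, obj$p, obj$n, byrow = TRUE),
                matrix(obj$D, obj$p, obj$m, byrow = TRUE),
                domain = obj$domain,
                dt = if (is.null(obj$dt)) NULL else obj$dt)
  } else stop("unknown system kind in ", path)
}
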