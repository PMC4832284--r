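#' Uniformly sampled skin-conductance signal
#'
#' Container for a single-channel, uniformly sampled skin-conductance (or
#' residual) trace. Values are in microsiemens after preprocessing; the
#' simulator and forward model produce values on the same scale.
#'
#' @param values Numeric vector of samples (microsiemens). Must be finite and
#'   of length at least 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time (s) of the first sample relative to the epoch start.
#' @return An object of class `sc_signal`: a list with elements `values`,
#'   `fs` and `t0`.
#' @examples
#' s <- sc_signal(rep(0, 600), fs = 10)
#' sc_duration(s)
#' @export
sc_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("'values' must contain at least one sample", call. = FALSE)
  if (!all(is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  structure(list(values = values, fs = fs, t0 = t0), class = "sc_signal")
}

#' @rdname sc_signal
#' @param x An `sc_signal`.
#' @export
sc_duration <- function(x) {
  stopifnot(inherits(x, "sc_signal"))
  length(x$values) / x$fs
}

#' Sample times of a signal
#' @param x An `sc_signal`.
#' @return Numeric vector of sample times (s).
#' @export
sc_times <- function(x) {
  stopifnot(inherits(x, "sc_signal"))
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' @export
print.sc_signal <- function(x, ...) {
  cat(sprintf("<sc_signal> %d samples @ %g Hz (%.1f s), range [%.4g, %.4g] uS\n",
              length(x$values), x$fs, sc_duration(x),
              min(x$values), max(x$values)))
  invisible(x)
}
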