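#' Peripheral response-function parameters
#'
#' Parameters of the peripheral model mapping sudomotor-nerve (SN) firing to
#' skin conductance: SF = SN * SCRF, with * the convolution operator and SCRF
#' the canonical skin conductance response function. The SCRF is realized as
#' a third-order linear time-invariant cascade of first-order lags, so the
#' impulse response is nonnegative, single-peaked, and decays exponentially.
#'
#' The default time constants give a response to a standard SN burst that
#' peaks about 2 s after the burst centre, recovers to half the peak about
#' 5 s later, and falls below 1e-4 of the peak within 60 s. The overall gain
#' is, by default, calibrated automatically at the analysis sampling rate so
#' that a unit-amplitude SN burst (Gaussian bump, SD `burst_sd`) evokes an SF
#' with exactly 1 microsiemens peak amplitude. This makes SN amplitude units
#' interchangeable with microsiemens of evoked SF.
#'
#' @param time_constants Three positive time constants (s) of the cascade.
#' @param gain `"auto"` (default) to calibrate the unit-burst peak to 1
#'   microsiemens at the sampling rate in use, or a fixed positive number.
#' @param burst_sd Standard deviation (s) of the standard SN burst used for
#'   calibration and as the default burst width (0.3 s).
#' @return An object of class `scrf_params`.
#' @examples
#' p <- scrf_params()
#' r <- canonical_response(p, fs = 10, horizon = 60)
#' max(r$values)  # 1 uS by calibration
#' @export
scrf_params <- function(time_constants = c(0.3, 0.7, 6.0), gain = "auto",
                        burst_sd = 0.3) {
  time_constants <- as.numeric(time_constants)
  if (length(time_constants) != 3L || !all(is.finite(time_constants)) ||
      any(time_constants <= 0))
    stop("'time_constants' must be three positive numbers (s)", call. = FALSE)
  if (!(identical(gain, "auto") ||
        (is.numeric(gain) && length(gain) == 1L && is.finite(gain) && gain > 0)))
    stop("'gain' must be \"auto\" or a single positive number", call. = FALSE)
  if (!is.numeric(burst_sd) || length(burst_sd) != 1L || burst_sd <= 0)
    stop("'burst_sd' must be a single positive number (s)", call. = FALSE)
  structure(list(time_constants = time_constants, gain = gain,
                 burst_sd = burst_sd),
            class = "scrf_params")
}

#' @export
print.scrf_params <- function(x, ...) {
  g <- if (identical(x$gain, "auto")) "auto (unit-burst peak = 1 uS)"
       else sprintf("%g", x$gain)
  cat(sprintf("<scrf_params> tau = (%s) s, gain = %s, burst sd = %g s\n",
              paste(x$time_constants, collapse = ", "), g, x$burst_sd))
  invisible(x)
}

#' Sudomotor-nerve burst
#'
#' A compact SN firing burst, modelled as a Gaussian bump in time. The bump
#' is truncated at 4 standard deviations on either side of its centre, which
#' discards less than 1e-4 of its mass and gives dictionary atoms compact
#' support.
#'
#' @param onset Centre of the bump (s), relative to the window start; may be
#'   negative (the burst's tail then enters the window).
#' @param amplitude Burst amplitude in SN units (>= 0; zero is a degenerate
#'   no-event burst).
#' @param sd Bump standard deviation (s), default 0.3.
#' @return An object of class `sn_burst`.
#' @export
sn_burst <- function(onset, amplitude = 1, sd = 0.3) {
  if (!is.numeric(onset) || length(onset) != 1L || !is.finite(onset))
    stop("'onset' must be a single finite number (s)", call. = FALSE)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("'amplitude' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("'sd' must be a single positive number (s)", call. = FALSE)
  structure(list(onset = onset, amplitude = amplitude, sd = sd),
            class = "sn_burst")
}

## ---- internal LTI machinery -------------------------------------------

# cascade of three first-order lags, unit DC gain per stage:
#   x1' = (u - x1)/tau1 ; x2' = (x1 - x2)/tau2 ; x3' = (x2 - x3)/tau3
.cascade_matrices <- function(tau) {
  A <- rbind(c(-1 / tau[1], 0, 0),
             c(1 / tau[2], -1 / tau[2], 0),
             c(0, 1 / tau[3], -1 / tau[3]))
  B <- c(1 / tau[1], 0, 0)
  list(A = A, B = B)
}

.sfmp_cache <- new.env(parent = emptyenv())

# Discrete unit-pulse response of the exactly discretized (zero-order-hold)
# cascade, gain excluded. Exact discretization removes integration step size
# as a source of numerical error: Ad = expm(A/fs), Bd = A^-1 (Ad - I) B.
.discrete_kernel <- function(params, fs, n) {
  key <- paste("kern", paste(format(params$time_constants, digits = 17),
                             collapse = ","), format(fs, digits = 17),
               sep = "|")
  hit <- .sfmp_cache[[key]]
  if (!is.null(hit) && length(hit) >= n) return(hit[seq_len(n)])
  m <- .cascade_matrices(params$time_constants)
  Ad <- as.matrix(Matrix::expm(m$A / fs))
  Bd <- solve(m$A, (Ad - diag(3)) %*% m$B)
  h <- numeric(n)
  x <- Bd
  if (n >= 2L) {
    for (k in 2:n) {
      h[k] <- x[3L]
      x <- Ad %*% x
    }
  }
  .sfmp_cache[[key]] <- h
  h
}

# peak of the (gain-free) sampled response to a unit-amplitude standard burst
.unit_peak <- function(params, fs) {
  sd <- params$burst_sd
  horizon <- 8 * sd + 8 * max(params$time_constants)
  n <- ceiling(horizon * fs)
  tt <- (seq_len(n) - 1L) / fs
  u <- exp(-(tt - 4 * sd)^2 / (2 * sd^2))
  u[abs(tt - 4 * sd) > 4 * sd] <- 0
  h <- .discrete_kernel(params, fs, n)
  y <- stats::convolve(u, rev(h), type = "open")[seq_len(n)]
  max(y)
}

.resolve_gain <- function(params, fs) {
  if (is.numeric(params$gain)) return(params$gain)
  key <- paste("gain", paste(format(params$time_constants, digits = 17),
                             collapse = ","),
               format(params$burst_sd, digits = 17),
               format(fs, digits = 17), sep = "|")
  hit <- .sfmp_cache[[key]]
  if (!is.null(hit)) return(hit)
  pk <- .unit_peak(params, fs)
  if (!is.finite(pk) || pk <= 0)
    stop("forward model response has no positive peak; ",
         "check time constants", call. = FALSE)
  g <- 1 / pk
  .sfmp_cache[[key]] <- g
  g
}

# Render a set of bursts through the peripheral model over [0, duration).
# Bursts with support before t = 0 are handled by extending the simulation
# grid backwards to the earliest support start (zero state there), so the
# within-window part of their response is included.
.render_bursts <- function(onsets, amplitudes, sds, params, duration, fs) {
  n <- round(duration * fs)
  if (n < 1L) stop("'duration' too short for the sampling rate", call. = FALSE)
  if (length(onsets) == 0L) return(numeric(n))
  sds <- rep_len(sds, length(onsets))
  m0 <- min(0, floor((min(onsets - 4 * sds)) * fs))
  n_ext <- n - m0
  u <- numeric(n_ext)
  for (i in seq_along(onsets)) {
    # 1e-9-sample slack keeps the truncation boundary stable under the
    # float noise of onset*fs, so integer-sample shifts commute exactly
    lo <- max(m0, ceiling((onsets[i] - 4 * sds[i]) * fs - 1e-9))
    hi <- min(n - 1L, floor((onsets[i] + 4 * sds[i]) * fs + 1e-9))
    if (lo > hi) next
    kk <- lo:hi
    u[kk - m0 + 1L] <- u[kk - m0 + 1L] +
      amplitudes[i] * exp(-(kk / fs - onsets[i])^2 / (2 * sds[i]^2))
  }
  h <- .discrete_kernel(params, fs, n_ext)
  y <- stats::convolve(u, rev(h), type = "open")[seq_len(n_ext)]
  g <- .resolve_gain(params, fs)
  (g * y)[(1L - m0):n_ext]
}

## ---- exported operations ----------------------------------------------

#' Evaluate an SN burst on a sample grid
#'
#' Returns the Gaussian bump of a single SN burst sampled at `fs` over
#' `n_samples` samples starting at t = 0, truncated to zero beyond four
#' standard deviations from the burst centre.
#'
#' @param burst An [sn_burst()].
#' @param fs Sampling rate (Hz).
#' @param n_samples Number of samples (>= 1).
#' @return An `sc_signal` in SN units.
#' @export
gaussian_bump <- function(burst, fs, n_samples) {
  if (!inherits(burst, "sn_burst")) burst <- do.call(sn_burst, burst)
  if (n_samples < 1L) stop("'n_samples' must be >= 1", call. = FALSE)
  tt <- (seq_len(n_samples) - 1L) / fs
  v <- burst$amplitude * exp(-(tt - burst$onset)^2 / (2 * burst$sd^2))
  v[abs(tt - burst$onset) > 4 * burst$sd + 1e-9 / fs] <- 0
  sc_signal(v, fs)
}

#' Canonical response to a standard SN burst
#'
#' The response of the peripheral model to a unit-amplitude SN burst
#' (Gaussian bump, SD `params$burst_sd`) centred at t = 0, sampled at `fs`
#' over `[0, horizon)`. With `gain = "auto"` (the default) the peak equals
#' 1 microsiemens by calibration.
#'
#' @param params [scrf_params()].
#' @param fs Sampling rate (Hz).
#' @param horizon Length of the returned response (s). Must be long enough
#'   for the response to decay; an error is raised if the final sample
#'   exceeds 1% of the peak.
#' @return An `sc_signal`.
#' @export
canonical_response <- function(params = scrf_params(), fs = 10, horizon = 60) {
  y <- .render_bursts(0, 1, params$burst_sd, params, horizon, fs)
  pk <- max(y)
  if (!is.finite(pk) || pk <= 0)
    stop("unstable or degenerate parameter set: response has no positive peak",
         call. = FALSE)
  if (y[length(y)] > 0.01 * pk)
    stop("response has not decayed within the horizon; increase 'horizon' ",
         "or check time constants", call. = FALSE)
  sc_signal(y, fs)
}

#' Simulate a skin-conductance trace from SN bursts
#'
#' Renders a burst train through the peripheral model: the superposition of
#' the responses to every burst, sampled at `fs` over `[0, duration)`. An
#' empty burst list yields an all-zero trace.
#'
#' @param bursts A list of [sn_burst()] objects, or a data frame with columns
#'   `onset`, `amplitude` and optionally `sd`.
#' @param params [scrf_params()].
#' @param duration Trace duration (s).
#' @param fs Sampling rate (Hz).
#' @return An `sc_signal` in microsiemens.
#' @examples
#' p <- scrf_params()
#' s <- simulate_sc(list(sn_burst(10, 1), sn_burst(30, 0.5)), p, 60, 10)
#' @export
simulate_sc <- function(bursts, params = scrf_params(), duration = 60,
                        fs = 10) {
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (is.data.frame(bursts)) {
    onsets <- bursts$onset
    amplitudes <- bursts$amplitude
    sds <- if (is.null(bursts$sd)) params$burst_sd else bursts$sd
  } else {
    bursts <- lapply(bursts, function(b) {
      if (inherits(b, "sn_burst")) b else do.call(sn_burst, as.list(b))
    })
    onsets <- vapply(bursts, `[[`, numeric(1), "onset")
    amplitudes <- vapply(bursts, `[[`, numeric(1), "amplitude")
    sds <- vapply(bursts, `[[`, numeric(1), "sd")
  }
  if (length(onsets) && (!all(is.finite(onsets)) || any(amplitudes < 0)))
    stop("burst onsets must be finite and amplitudes nonnegative",
         call. = FALSE)
  y <- .render_bursts(onsets, amplitudes,
                      if (length(onsets)) sds else numeric(0),
                      params, duration, fs)
  sc_signal(y, fs)
}
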