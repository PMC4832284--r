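#' Simulation protocol specification
#'
#' Conditions of the synthetic-data protocol: 60-s traces at 10 Hz, SN bursts
#' as Gaussian bumps (SD 0.3 s), burst amplitudes uniform on [0.1, 2.0] SN
#' units, and inter-burst intervals drawn from an exponential distribution
#' (mean = 60 / target rate seconds) plus a 1-s refractory period, so bursts
#' are always separated by at least 1 s.
#'
#' @param target_rate Desired burst frequency (per minute, >= 1).
#' @param duration Trace duration (s), default 60.
#' @param fs Sampling rate (Hz), default 10.
#' @param burst_sd Burst bump SD (s), default 0.3.
#' @param amp_low,amp_high Amplitude range (SN units), default 0.1 and 2.0.
#' @param refractory Minimum burst separation (s), default 1.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(target_rate = 10, duration = 60, fs = 10,
                     burst_sd = 0.3, amp_low = 0.1, amp_high = 2.0,
                     refractory = 1) {
  if (target_rate < 1) stop("'target_rate' must be >= 1", call. = FALSE)
  if (amp_low >= amp_high) stop("'amp_low' must be < 'amp_high'", call. = FALSE)
  if (refractory < 0) stop("'refractory' must be >= 0", call. = FALSE)
  structure(list(target_rate = target_rate, duration = duration, fs = fs,
                 burst_sd = burst_sd, amp_low = amp_low, amp_high = amp_high,
                 refractory = refractory),
            class = "sim_spec")
}

#' Draw SN burst onsets
#'
#' Onsets accumulate from the window start: each inter-burst interval is an
#' exponential draw with mean `60 / target_rate` seconds plus the refractory
#' period, so consecutive onsets are separated by at least the refractory
#' period. Draws use R's global random number generator; seed with
#' [set.seed()] for reproducibility.
#'
#' @param spec A [sim_spec()].
#' @return Sorted numeric vector of onsets (s) in `[0, duration)`; empty when
#'   `duration` is 0.
#' @export
draw_onsets <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$duration <= 0) return(numeric(0))
  mean_iv <- 60 / spec$target_rate
  onsets <- numeric(0)
  t <- 0
  repeat {
    iv <- stats::rexp(16L, rate = 1 / mean_iv) + spec$refractory
    cand <- t + cumsum(iv)
    onsets <- c(onsets, cand[cand < spec$duration])
    t <- cand[length(cand)]
    if (t >= spec$duration) break
  }
  onsets
}

#' Draw SN burst amplitudes
#'
#' @param n Number of draws (>= 0).
#' @param spec A [sim_spec()].
#' @return `n` independent uniform draws on `[amp_low, amp_high]`.
#' @export
draw_amplitudes <- function(n, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  stats::runif(n, spec$amp_low, spec$amp_high)
}

#' Simulate one trace with known ground truth
#'
#' Draws a burst train under `spec`, renders it through the peripheral model
#' and returns the trace together with the true bursts. A burst belongs to
#' the trace when its bump centre lies in `[0, duration)`, matching the
#' dictionary's onset convention.
#'
#' @param spec A [sim_spec()].
#' @param params [scrf_params()].
#' @return A list with `signal` (an `sc_signal`) and `truth` (data frame with
#'   columns `onset`, `amplitude`).
#' @export
simulate_trace <- function(spec, params = scrf_params()) {
  onsets <- draw_onsets(spec)
  amplitudes <- draw_amplitudes(length(onsets), spec)
  truth <- data.frame(onset = onsets, amplitude = amplitudes)
  signal <- simulate_sc(truth, params, spec$duration, spec$fs)
  list(signal = signal, truth = truth)
}

#' Generate a corpus binned by realized burst count
#'
#' Burst trains are generated and each assigned to the bin equal to its
#' realized number of bursts, until every requested bin holds `n_per_bin`
#' traces; only accepted trains are rendered through the forward model.
#' Because the refractory period makes the realized count fall short of the
#' nominal rate (a target rate of r per minute realizes about 60r/(60+r)
#' bursts in 60 s), candidate trains for each still-unfilled bin k are drawn
#' at the matched target rate 60k/(duration - k) per minute, cycling over
#' unfilled bins, so every bin fills in bounded time while the binning
#' contract (bin label = realized count) is preserved exactly.
#'
#' @param bins Integer vector of requested realized burst counts.
#' @param n_per_bin Traces per bin (>= 1); 1000 replicates the full protocol.
#' @param spec A [sim_spec()]; its `target_rate` is overridden per draw.
#' @param params [scrf_params()].
#' @param seed Optional integer seed; the same seed yields an identical
#'   corpus. Per accepted trace, onsets are drawn first, then amplitudes.
#' @param max_draws Maximum candidate trains per bin before an unreachable
#'   bin is reported as an error (default `1000 * n_per_bin`).
#' @return An object of class `sf_corpus`: a list of entries, each with
#'   `bin`, `signal` and `truth`, plus attributes `bins` and `n_per_bin`.
#' @export
generate_corpus <- function(bins, n_per_bin = 100, spec = sim_spec(),
                            params = scrf_params(), seed = NULL,
                            max_draws = 1000 * n_per_bin) {
  if (n_per_bin < 1L) stop("'n_per_bin' must be >= 1", call. = FALSE)
  bins <- sort(unique(as.integer(bins)))
  if (any(bins < 1L)) stop("'bins' must be positive counts", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  need <- stats::setNames(rep(n_per_bin, length(bins)), bins)
  draws <- stats::setNames(rep(0L, length(bins)), bins)
  entries <- vector("list", n_per_bin * length(bins))
  n_kept <- 0L
  while (any(need > 0L)) {
    for (k in bins[need[as.character(bins)] > 0L]) {
      kc <- as.character(k)
      rate_k <- 60 * k / max(spec$duration - k * spec$refractory,
                             spec$duration / 2)
      sp <- spec
      sp$target_rate <- max(1, rate_k)
      onsets <- draw_onsets(sp)
      draws[kc] <- draws[kc] + 1L
      if (draws[kc] > max_draws && need[kc] > 0L)
        stop(sprintf(
          "bin %d unreachable: %d candidate trains drawn without filling it",
          k, draws[kc] - 1L), call. = FALSE)
      m <- length(onsets)
      mc <- as.character(m)
      if (!mc %in% names(need) || need[mc] == 0L) next
      amplitudes <- draw_amplitudes(m, sp)
      truth <- data.frame(onset = onsets, amplitude = amplitudes)
      n_kept <- n_kept + 1L
      entries[[n_kept]] <- list(
        bin = m,
        signal = simulate_sc(truth, params, spec$duration, spec$fs),
        truth = truth)
      need[mc] <- need[mc] - 1L
    }
  }
  structure(entries[seq_len(n_kept)], bins = bins, n_per_bin = n_per_bin,
            class = "sf_corpus")
}

#' @export
print.sf_corpus <- function(x, ...) {
  cat(sprintf("<sf_corpus> %d traces, bins {%s}, %d per bin\n",
              length(x), paste(attr(x, "bins"), collapse = ", "),
              attr(x, "n_per_bin")))
  invisible(x)
}
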