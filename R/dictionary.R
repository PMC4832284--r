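#' Build the overcomplete SF dictionary
#'
#' The dictionary holds every SF waveform that could be observed under the
#' forward model within the data window: one atom per candidate SN-burst
#' onset, with onsets running from 9 s before data onset to 1 s after data
#' offset in steps of 0.1 s. Each atom is the within-window response to a
#' unit-amplitude SN burst at that onset; for a 60-s trace this yields 701
#' atoms. Atoms near the window edges are truncated by the window, so their
#' l2 norms differ; the norms are stored for use by the normalized greedy
#' selection rule.
#'
#' @param n_samples Number of data samples (>= 1).
#' @param fs Sampling rate (Hz). Onsets are kept on their own 0.1-s grid
#'   regardless of `fs`.
#' @param params [scrf_params()].
#' @param onset_step Onset spacing (s), default 0.1.
#' @param onset_before Seconds before data onset covered by the onset grid
#'   (default 9).
#' @param onset_after Seconds after data offset covered (default 1).
#' @return An object of class `sf_dictionary`: list with `onsets`, `atoms`
#'   (an `n_samples` x n_onsets matrix), `norms`, `fs`, `n_samples`,
#'   `duration` and `params`.
#' @examples
#' d <- build_dictionary(600, 10, scrf_params())
#' length(d$onsets)  # 701
#' @export
build_dictionary <- function(n_samples, fs, params = scrf_params(),
                             onset_step = 0.1, onset_before = 9,
                             onset_after = 1) {
  if (n_samples < 1L) stop("'n_samples' must be >= 1", call. = FALSE)
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  duration <- n_samples / fs
  ticks <- seq.int(round(-onset_before / onset_step),
                   round((duration + onset_after) / onset_step))
  onsets <- ticks * onset_step
  atoms <- matrix(0, nrow = n_samples, ncol = length(onsets))
  for (k in seq_along(onsets)) {
    atoms[, k] <- .render_bursts(onsets[k], 1, params$burst_sd, params,
                                 duration, fs)
  }
  norms <- sqrt(colSums(atoms^2))
  keep <- norms > 0
  structure(list(onsets = onsets[keep],
                 atoms = atoms[, keep, drop = FALSE],
                 norms = norms[keep],
                 fs = fs, n_samples = as.integer(n_samples),
                 duration = duration, params = params),
            class = "sf_dictionary")
}

#' @export
print.sf_dictionary <- function(x, ...) {
  cat(sprintf(
    "<sf_dictionary> %d atoms over [%.1f, %.1f] s, %d samples @ %g Hz\n",
    length(x$onsets), min(x$onsets), max(x$onsets), x$n_samples, x$fs))
  invisible(x)
}
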