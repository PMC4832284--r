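#' Greedy nearest-in-time matching of true and estimated SF
#'
#' Pairs estimated SF with true SF by repeatedly taking the globally smallest
#' absolute time difference among the still-unpaired items, until one side is
#' exhausted; each true and each estimated SF is used at most once. Ties in
#' the time difference are broken towards the earlier true onset, then the
#' earlier estimated onset (the rule is a convention; results are reported
#' with it fixed).
#'
#' @param true_onsets,est_onsets Numeric onset vectors (s); sorted internally.
#' @return An object of class `sf_match`: `pairs` (data frame with
#'   `true_index`, `est_index`, `time_diff` = estimated - true, in s, indices
#'   into the sorted vectors), `true_onsets`, `est_onsets` (sorted),
#'   `unmatched_true`, `unmatched_est` (index vectors).
#' @examples
#' greedy_match(c(10, 20), 19)
#' @export
greedy_match <- function(true_onsets, est_onsets) {
  tr <- sort(as.numeric(true_onsets))
  es <- sort(as.numeric(est_onsets))
  nt <- length(tr)
  ne <- length(es)
  np <- min(nt, ne)
  pairs <- data.frame(true_index = integer(np), est_index = integer(np),
                      time_diff = numeric(np))
  if (np > 0L) {
    d <- abs(outer(tr, es, "-"))
    avail_t <- rep(TRUE, nt)
    avail_e <- rep(TRUE, ne)
    for (p in seq_len(np)) {
      dd <- d[avail_t, avail_e, drop = FALSE]
      m <- min(dd)
      cand <- which(d == m & outer(avail_t, avail_e, "&"), arr.ind = TRUE)
      cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
      i <- cand[1L, 1L]
      j <- cand[1L, 2L]
      pairs$true_index[p] <- i
      pairs$est_index[p] <- j
      pairs$time_diff[p] <- es[j] - tr[i]
      avail_t[i] <- FALSE
      avail_e[j] <- FALSE
    }
  } else {
    avail_t <- rep(TRUE, nt)
    avail_e <- rep(TRUE, ne)
  }
  structure(list(pairs = pairs, true_onsets = tr, est_onsets = es,
                 unmatched_true = which(avail_t),
                 unmatched_est = which(avail_e)),
            class = "sf_match")
}

#' @export
print.sf_match <- function(x, ...) {
  cat(sprintf("<sf_match> %d pairs, %d unmatched true, %d unmatched estimated\n",
              nrow(x$pairs), length(x$unmatched_true),
              length(x$unmatched_est)))
  invisible(x)
}

#' RMSE of estimated SF counts
#'
#' @param true_counts,est_counts Numeric vectors of equal positive length
#'   (one entry per trace).
#' @return Root mean squared error between the counts.
#' @export
rmse_counts <- function(true_counts, est_counts) {
  if (length(true_counts) < 1L || length(true_counts) != length(est_counts))
    stop("count vectors must be nonempty and of equal length", call. = FALSE)
  sqrt(mean((est_counts - true_counts)^2))
}

#' RMSE of matched amplitudes or onsets
#'
#' Computed over matched pairs only; unmatched true and estimated SF are
#' ignored.
#'
#' @param match An [greedy_match()] result.
#' @param true_values,est_values Values aligned with the *sorted* true and
#'   estimated onsets (e.g. amplitudes); for onset RMSE pass the onsets
#'   themselves.
#' @return RMSE over the matched pairs.
#' @export
rmse_matched <- function(match, true_values, est_values) {
  stopifnot(inherits(match, "sf_match"))
  if (nrow(match$pairs) < 1L)
    stop("no matched pairs; RMSE undefined", call. = FALSE)
  e <- est_values[match$pairs$est_index] - true_values[match$pairs$true_index]
  sqrt(mean(e^2))
}

#' Benchmark the pipeline on a simulated corpus
#'
#' Runs [estimate_sf()] on every trace (sharing one dictionary), matches
#' estimated to true SF with [greedy_match()], and aggregates per bin. True
#' amplitudes are ordered by onset; estimated SF are the above-threshold
#' reestimated bursts. Onsets are compared as SN-burst onsets on both sides
#' (no conduction delay). Amplitude and onset RMSE pool matched pairs over
#' all traces of the bin; bins whose traces produced no matched pairs report
#' `NA`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param params [scrf_params()].
#' @param cfg [mp_config()].
#' @return Data frame with one row per bin: `bin`, `n_traces`, `mean_est`,
#'   `rmse_count`, `rmse_amplitude`, `rmse_onset`.
#' @export
benchmark_corpus <- function(corpus, params = scrf_params(),
                             cfg = mp_config()) {
  stopifnot(inherits(corpus, "sf_corpus"))
  if (length(corpus) < 1L) stop("empty corpus", call. = FALSE)
  n0 <- length(corpus[[1L]]$signal$values)
  fs <- corpus[[1L]]$signal$fs
  dict <- build_dictionary(n0, fs, params)
  rows <- lapply(corpus, function(e) {
    est <- estimate_sf(e$signal, params, cfg, dictionary = dict)
    tr <- e$truth[order(e$truth$onset), , drop = FALSE]
    mt <- greedy_match(tr$onset, est$onsets)
    a <- est$amplitudes[est$amplitudes >= cfg$amp_threshold &
                          est$amplitudes > 0]
    sq_amp <- if (nrow(mt$pairs))
      (a[mt$pairs$est_index] - tr$amplitude[mt$pairs$true_index])^2
    else numeric(0)
    sq_on <- mt$pairs$time_diff^2
    list(bin = e$bin, est_count = est$count, sq_amp = sq_amp, sq_on = sq_on)
  })
  bins <- sort(unique(vapply(rows, `[[`, numeric(1), "bin")))
  out <- do.call(rbind, lapply(bins, function(b) {
    rb <- rows[vapply(rows, function(r) r$bin == b, logical(1))]
    ec <- vapply(rb, `[[`, numeric(1), "est_count")
    sa <- unlist(lapply(rb, `[[`, "sq_amp"))
    so <- unlist(lapply(rb, `[[`, "sq_on"))
    data.frame(bin = b, n_traces = length(rb), mean_est = mean(ec),
               rmse_count = sqrt(mean((ec - b)^2)),
               rmse_amplitude = if (length(sa)) sqrt(mean(sa)) else NA_real_,
               rmse_onset = if (length(so)) sqrt(mean(so)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
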