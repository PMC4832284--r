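#' Matching-pursuit configuration
#'
#' Tuning constants of the greedy search and the SF counting rule.
#'
#' The search stops when the residual l2 norm falls below
#' `sqrt(eps_factor * N)` (N data samples), when the number of selected atoms
#' reaches `ceiling(max_rate * minutes)`, or when no atom with a positive
#' coefficient remains. The defaults are eps_factor 0.001 and a cap of 30 SF
#' per minute of data, matching the fixed SF capacity of the generative
#' model. SF whose reestimated amplitude is at least `amp_threshold` (default
#' 0.1 microsiemens, the recommended scoring criterion) are counted towards
#' the arousal estimate.
#'
#' @param eps_factor Factor in the residual stopping norm (> 0).
#' @param max_rate Maximum number of SF per minute of data (> 0).
#' @param amp_threshold Minimum reestimated amplitude (microsiemens) for an
#'   SF to be counted (>= 0).
#' @param normalize Logical; if `TRUE` (default) the greedy selection
#'   maximizes the norm-normalized signed inner product `<g, R>/||g||` (the
#'   classical matching-pursuit criterion), if `FALSE` the plain signed inner
#'   product. In both cases the applied coefficient is `<g, R>/||g||^2`, the
#'   optimal one-dimensional projection, so coefficients are in SN-amplitude
#'   units.
#' @param conduction_delay Peripheral conduction delay (s, >= 0) subtracted
#'   from SN onsets when central SF times are reported; default 0.
#' @return An object of class `mp_config`.
#' @export
mp_config <- function(eps_factor = 0.001, max_rate = 30, amp_threshold = 0.1,
                      normalize = TRUE, conduction_delay = 0) {
  if (eps_factor <= 0) stop("'eps_factor' must be > 0", call. = FALSE)
  if (max_rate <= 0) stop("'max_rate' must be > 0", call. = FALSE)
  if (amp_threshold < 0) stop("'amp_threshold' must be >= 0", call. = FALSE)
  if (conduction_delay < 0)
    stop("'conduction_delay' must be >= 0", call. = FALSE)
  structure(list(eps_factor = eps_factor, max_rate = max_rate,
                 amp_threshold = amp_threshold,
                 normalize = isTRUE(normalize),
                 conduction_delay = conduction_delay),
            class = "mp_config")
}

#' Greedy matching-pursuit search
#'
#' Decomposes a skin-conductance trace over the SF dictionary. On each
#' iteration the atom maximizing the signed (normalized) inner product with
#' the current residual is selected, its optimal contribution
#' `a = <g, R>/||g||^2` subtracted, and the residual updated. Maximizing the
#' signed rather than absolute inner product enforces nonnegative SF: a best
#' coefficient <= 0 terminates the search without being applied. The other
#' stopping rules are the residual norm falling below
#' `eps = sqrt(eps_factor * N)` and the per-minute iteration cap (see
#' [mp_config()]). Ties in the argmax are broken towards the earliest onset.
#'
#' @param data An [sc_signal()] on the dictionary's grid.
#' @param dict An [build_dictionary()] result.
#' @param cfg An [mp_config()].
#' @return An object of class `mp_result`: `selected_onsets`,
#'   `selected_index`, `greedy_coefficients`, `residual` (`sc_signal`),
#'   `residual_norms` (after each iteration), `stop_reason` (one of
#'   `"residual_below_eps"`, `"max_iterations"`,
#'   `"nonpositive_coefficient"`), `n_iterations`, `eps`, `max_iter`.
#' @export
mp_search <- function(data, dict, cfg = mp_config()) {
  stopifnot(inherits(data, "sc_signal"), inherits(dict, "sf_dictionary"))
  if (length(dict$onsets) < 1L)
    stop("empty dictionary", call. = FALSE)
  if (length(data$values) != dict$n_samples || data$fs != dict$fs)
    stop("data is not sampled on the dictionary's grid", call. = FALSE)
  R <- data$values
  N <- length(R)
  eps <- sqrt(cfg$eps_factor * N)
  max_iter <- ceiling(cfg$max_rate * dict$duration / 60)
  sel <- integer(0)
  coefs <- numeric(0)
  rnorms <- numeric(0)
  stop_reason <- if (sqrt(sum(R^2)) < eps) "residual_below_eps" else NULL
  while (is.null(stop_reason)) {
    if (length(sel) >= max_iter) {
      stop_reason <- "max_iterations"
      break
    }
    ip <- drop(crossprod(dict$atoms, R))
    crit <- if (cfg$normalize) ip / dict$norms else ip
    j <- which.max(crit)   # first maximum = earliest onset on ties
    # numerically-zero best coefficient counts as nonpositive: once an atom's
    # optimal projection is removed its inner product is float noise, and
    # reselecting it would make no progress
    if (crit[j] <= 1e-10 * sqrt(sum(R^2))) {
      stop_reason <- "nonpositive_coefficient"
      break
    }
    a <- ip[j] / dict$norms[j]^2
    R <- R - a * dict$atoms[, j]
    sel <- c(sel, j)
    coefs <- c(coefs, a)
    rn <- sqrt(sum(R^2))
    rnorms <- c(rnorms, rn)
    if (rn < eps) stop_reason <- "residual_below_eps"
  }
  structure(list(selected_onsets = dict$onsets[sel],
                 selected_index = sel,
                 greedy_coefficients = coefs,
                 residual = sc_signal(R, data$fs),
                 residual_norms = rnorms,
                 stop_reason = stop_reason,
                 n_iterations = length(sel),
                 eps = eps, max_iter = max_iter),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf(
    "<mp_result> %d iterations, stop: %s, final residual norm %.4g (eps %.4g)\n",
    x$n_iterations, x$stop_reason,
    sqrt(sum(x$residual$values^2)), x$eps))
  invisible(x)
}

# minimum-norm least squares via SVD (used when the atom set is
# rank-deficient, e.g. duplicated or near-collinear atoms)
.minnorm_lsq <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  pos <- s$d > tol
  drop(s$v[, pos, drop = FALSE] %*%
         ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos]))
}

#' Reestimate SF amplitudes by multiple regression
#'
#' The greedy search mis-splits amplitude between overlapping SF: it
#' overestimates one and underestimates the other. Amplitudes of all
#' selected atoms are therefore reestimated jointly, as the least-squares
#' weights of the selected atoms regressed on the data (no intercept: the
#' high-pass preprocessing removes baseline level). Duplicate onsets are
#' merged into a single predictor. The regression residual is orthogonal to
#' every selected atom.
#'
#' @param data An [sc_signal()] on the dictionary's grid.
#' @param dict An [build_dictionary()] result.
#' @param selected_onsets Onsets (s) of the selected atoms; must lie on the
#'   dictionary's onset grid.
#' @return Named numeric vector of amplitudes (SN units, approximately
#'   microsiemens of evoked SF peak), one per unique onset in ascending
#'   order, with attributes `onsets` and `rank_deficient` (logical; `TRUE`
#'   when the minimum-norm solution was used).
#' @export
reestimate_amplitudes <- function(data, dict, selected_onsets) {
  stopifnot(inherits(data, "sc_signal"), inherits(dict, "sf_dictionary"))
  if (length(selected_onsets) < 1L)
    stop("at least one selected onset is required", call. = FALSE)
  onsets <- sort(unique(selected_onsets))
  idx <- match(round(onsets, 10), round(dict$onsets, 10))
  if (anyNA(idx))
    stop("selected onsets not on the dictionary grid: ",
         paste(onsets[is.na(idx)], collapse = ", "), call. = FALSE)
  X <- dict$atoms[, idx, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    w <- .minnorm_lsq(X, data$values)
    deficient <- TRUE
  } else {
    w <- drop(qr.coef(qx, data$values))
    deficient <- FALSE
  }
  names(w) <- format(onsets)
  attr(w, "onsets") <- onsets
  attr(w, "rank_deficient") <- deficient
  w
}

#' Count above-threshold SF
#'
#' The number of SF whose reestimated amplitude reaches the amplitude
#' threshold is the estimate of tonic sympathetic arousal; it is also
#' expressed as a rate per minute.
#'
#' @param amplitudes Numeric vector of reestimated amplitudes.
#' @param cfg An [mp_config()] (provides `amp_threshold`).
#' @param duration Data duration (s, > 0).
#' @return A list with `count` and `rate_per_min`.
#' @export
count_sf <- function(amplitudes, cfg = mp_config(), duration) {
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  count <- sum(amplitudes >= cfg$amp_threshold & amplitudes > 0)
  list(count = as.integer(count), rate_per_min = count / (duration / 60))
}

#' Convert SN onsets to central SF times
#'
#' The peripheral model does not include nerve conduction delay; when the
#' time of central SF generation is required, the (nonnegative) conduction
#' delay is subtracted from the estimated SN burst onsets.
#'
#' @param selected_onsets Estimated SN onsets (s).
#' @param conduction_delay Delay (s, >= 0).
#' @return `selected_onsets - conduction_delay`.
#' @export
report_sf_onsets <- function(selected_onsets, conduction_delay = 0) {
  if (conduction_delay < 0)
    stop("'conduction_delay' must be >= 0", call. = FALSE)
  selected_onsets - conduction_delay
}

#' Full SF estimation pipeline
#'
#' Runs dictionary construction (unless a prebuilt dictionary is supplied),
#' the greedy matching-pursuit search, amplitude reestimation and
#' above-threshold counting on one preprocessed trace.
#'
#' @param data An [sc_signal()] (microsiemens, preprocessed).
#' @param params [scrf_params()].
#' @param cfg [mp_config()].
#' @param dictionary Optional prebuilt [build_dictionary()] matching the data
#'   grid; building it once and reusing it across traces of equal length is
#'   much faster.
#' @return An object of class `sf_estimate`: `count`, `rate_per_min`,
#'   `onsets` (SN onsets, s), `central_onsets` (conduction delay removed),
#'   `amplitudes` (all reestimated amplitudes, named by onset),
#'   `rank_deficient`, `stop_reason`, `n_iterations`, `residual_norm`,
#'   `threshold`, `duration` and the `mp` result.
#' @examples
#' p <- scrf_params()
#' y <- simulate_sc(list(sn_burst(20, 0.8)), p, 60, 10)
#' est <- estimate_sf(y, p)
#' est$count
#' @export
estimate_sf <- function(data, params = scrf_params(), cfg = mp_config(),
                        dictionary = NULL) {
  stopifnot(inherits(data, "sc_signal"))
  dict <- if (is.null(dictionary))
    build_dictionary(length(data$values), data$fs, params)
  else dictionary
  mp <- mp_search(data, dict, cfg)
  if (mp$n_iterations == 0L) {
    amps <- numeric(0)
    onsets <- numeric(0)
    deficient <- FALSE
  } else {
    amps <- reestimate_amplitudes(data, dict, mp$selected_onsets)
    onsets <- attr(amps, "onsets")
    deficient <- attr(amps, "rank_deficient")
  }
  counted <- count_sf(amps, cfg, dict$duration)
  keep <- amps >= cfg$amp_threshold & amps > 0
  structure(list(count = counted$count,
                 rate_per_min = counted$rate_per_min,
                 onsets = onsets[keep],
                 central_onsets = report_sf_onsets(onsets[keep],
                                                   cfg$conduction_delay),
                 amplitudes = amps,
                 rank_deficient = deficient,
                 stop_reason = mp$stop_reason,
                 n_iterations = mp$n_iterations,
                 residual_norm = sqrt(sum(mp$residual$values^2)),
                 threshold = cfg$amp_threshold,
                 duration = dict$duration,
                 mp = mp),
            class = "sf_estimate")
}

#' @export
print.sf_estimate <- function(x, ...) {
  cat(sprintf(
    "<sf_estimate> %d SF >= %.3g uS (%.2f per min) in %.1f s; %d MP iterations, stop: %s\n",
    x$count, x$threshold, x$rate_per_min, x$duration,
    x$n_iterations, x$stop_reason))
  if (x$count > 0) {
    cat("  onset (s) amplitude (uS)\n")
    a <- x$amplitudes[x$amplitudes >= x$threshold & x$amplitudes > 0]
    for (i in seq_along(x$onsets))
      cat(sprintf("  %9.1f %14.3f\n", x$onsets[i], a[i]))
  }
  invisible(x)
}
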