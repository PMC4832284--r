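#' Read a raw skin-conductance recording
#'
#' Reads a single-channel recording from a plain-text file: either one value
#' per line (no header), or a CSV/TSV file with a header from which a named
#' column is taken. The sampling rate is supplied by the caller and attached
#' to the result.
#'
#' @param path Path to the file.
#' @param fs Sampling rate (Hz). Common acquisition rates are 10, 100 and
#'   1000 Hz; any positive rate is accepted, with a warning for unusual ones.
#' @param column Column name for CSV/TSV input; `NULL` (default) for
#'   single-column text.
#' @param sep Field separator for delimited input; guessed from the file
#'   extension (`.csv` comma, `.tsv` tab) when `NULL`.
#' @return An `sc_signal` with attributes `channel` and `source`.
#' @export
read_recording <- function(path, fs, column = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!fs %in% c(10, 100, 1000))
    warning("unusual sampling rate ", fs, " Hz; typical rates are 10, 100 ",
            "or 1000 Hz", call. = FALSE)
  if (is.null(column)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
      stop("empty input file: ", path, call. = FALSE)
    v <- suppressWarnings(as.numeric(lines))
    if (anyNA(v))
      stop(sprintf("non-numeric value at line %d of %s: '%s'",
                   which(is.na(v))[1L], path, lines[which(is.na(v))[1L]]),
           call. = FALSE)
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("empty input file: ", path, call. = FALSE)
    if (!column %in% names(tab))
      stop("column '", column, "' not found; available: ",
           paste(names(tab), collapse = ", "), call. = FALSE)
    v <- suppressWarnings(as.numeric(tab[[column]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value at data line %d of %s",
                   which(is.na(v))[1L], path), call. = FALSE)
  }
  out <- sc_signal(v, fs)
  attr(out, "channel") <- if (is.null(column)) NA_character_ else column
  attr(out, "source") <- path
  out
}

#' Causal Butterworth band-pass filter
#'
#' Applies the preprocessing band-pass: a unidirectional (single-pass,
#' forward-only, i.e. causal) Butterworth filter with cutoffs 0.0159 Hz and
#' 5 Hz by default, realized as a cascade of a high-pass and a low-pass
#' section for numerical stability at the extreme cutoff ratio. The phase
#' delay of the causal pass is accepted. If the upper cutoff reaches the
#' Nyquist frequency it is clipped just below it, with a warning.
#'
#' @param rec An `sc_signal`.
#' @param low,high Cutoff frequencies (Hz), defaults 0.0159 and 5.
#' @param order Filter order per section (default 2).
#' @return The filtered `sc_signal` at the same sampling rate.
#' @export
bandpass <- function(rec, low = 0.0159, high = 5, order = 2) {
  stopifnot(inherits(rec, "sc_signal"))
  if (low <= 0 || high <= low)
    stop("cutoffs must satisfy 0 < low < high", call. = FALSE)
  nyq <- rec$fs / 2
  if (high >= nyq) {
    high <- 0.99 * nyq
    warning(sprintf("upper cutoff clipped to %.3g Hz (just below Nyquist)",
                    high), call. = FALSE)
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  v <- signal::filter(lp, signal::filter(hp, rec$values))
  out <- sc_signal(as.numeric(v), rec$fs, rec$t0)
  attributes(out)[c("channel", "source")] <-
    attributes(rec)[c("channel", "source")]
  out
}

#' Downsample a recording to the 10 Hz analysis grid
#'
#' Keeps every k-th sample (k = fs / 10); the 5 Hz low-pass of [bandpass()]
#' serves as the anti-alias filter and must be applied first for rates above
#' 10 Hz. Sampling rates that are not integer multiples of 10 are rejected.
#'
#' @param rec An `sc_signal`.
#' @param target_hz Target rate (Hz), default 10.
#' @return An `sc_signal` at `target_hz`.
#' @export
downsample_to_10hz <- function(rec, target_hz = 10) {
  stopifnot(inherits(rec, "sc_signal"))
  k <- rec$fs / target_hz
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("sampling rate ", rec$fs, " Hz is not an integer multiple of ",
         target_hz, " Hz; resample explicitly before analysis",
         call. = FALSE)
  k <- as.integer(round(k))
  out <- sc_signal(rec$values[seq.int(1L, length(rec$values), by = k)],
                   target_hz, rec$t0)
  attributes(out)[c("channel", "source")] <-
    attributes(rec)[c("channel", "source")]
  out
}

#' Standard preprocessing chain
#'
#' Band-pass filter then downsample to the analysis grid.
#'
#' @inheritParams bandpass
#' @inheritParams downsample_to_10hz
#' @return An `sc_signal` at `target_hz`.
#' @export
preprocess_recording <- function(rec, low = 0.0159, high = 5, order = 2,
                                 target_hz = 10) {
  f <- bandpass(rec, low = low, high = high, order = order)
  if (rec$fs == target_hz) f else downsample_to_10hz(f, target_hz)
}
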