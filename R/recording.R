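#' In-memory EEG recording
#'
#' The container every processing stage transforms: a channels x samples
#' matrix of amplitudes in microvolts, a sampling rate, per-channel 10-20
#' labels, and a provenance tag recording how far along the correction
#' chain the data are (`"raw"` for uncorrected input, `"post_obs"` after
#' template subtraction, `"post_ica"` after component removal).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param labels character vector of unique channel names, one per row.
#' @param stage provenance tag: one of `"raw"`, `"post_obs"`, `"post_ica"`.
#' @param meta optional named list of free-form metadata (kept on copy).
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2), fs = 250, labels = c("C3", "C4"))
#' n_samples(rec)
#' @export
eeg_recording <- function(data, fs, labels, stage = "raw", meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1L)
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive finite number")
  labels <- as.character(labels)
  if (nrow(data) != length(labels))
    stop("row count (", nrow(data), ") must equal label count (", length(labels), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  stage <- match.arg(stage, c("raw", "post_obs", "post_ica"))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, stage = stage, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), stage=%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$stage))
  invisible(x)
}

#' @rdname eeg_recording
#' @param x an `eeg_recording`.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname eeg_recording
#' @export
n_channels <- function(x) nrow(x$data)

#' R-peak series
#'
#' Ordered sample positions (1-based) of ECG R peaks, defining the cardiac
#' cycle grid used for pulse-artifact epoching.
#'
#' @param indices strictly increasing integer sample positions (1-based).
#' @param fs sampling rate in Hz; must equal the recording's when used together.
#' @param n_total optional recording length for bounds checking.
#' @return An object of class `rpeak_series`.
#' @export
rpeak_series <- function(indices, fs, n_total = NULL) {
  indices <- as.integer(round(indices))
  if (length(indices) < 2L) stop("need at least 2 R peaks (an R-R interval must exist)")
  if (any(diff(indices) <= 0L)) stop("R-peak indices must be strictly increasing")
  if (any(indices < 1L)) stop("R-peak indices must be >= 1")
  if (!is.null(n_total) && any(indices > n_total))
    stop("R-peak indices exceed recording bounds")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(indices = indices, fs = fs), class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  rr <- diff(x$indices) / x$fs
  cat(sprintf("<rpeak_series> %d peaks @ %g Hz, mean R-R %.3f s (sd %.3f)\n",
              length(x$indices), x$fs, mean(rr), stats::sd(rr)))
  invisible(x)
}

#' Mean R-R interval, in samples
#' @param rpeaks an `rpeak_series`.
#' @return mean inter-peak distance in samples.
#' @export
mean_rr_samples <- function(rpeaks) mean(diff(rpeaks$indices))

#' Epoch window relative to R peaks
#'
#' @param start_ms,end_ms window edges in milliseconds relative to each R
#'   peak; `end_ms > start_ms`. The pulse-artifact window is 0--700 ms and
#'   the validation window is -200--1000 ms.
#' @return An object of class `epoch_window`.
#' @export
epoch_window <- function(start_ms, end_ms) {
  stopifnot(is.numeric(start_ms), is.numeric(end_ms))
  if (end_ms <= start_ms) stop("end_ms must exceed start_ms")
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "epoch_window")
}

#' @rdname epoch_window
#' @param window an `epoch_window`.
#' @param fs sampling rate in Hz.
#' @return `window_samples`: number of samples in the half-open window
#'   `[start, end)` after converting to samples.
#' @export
window_samples <- function(window, fs) {
  as.integer(round((window$end_ms - window$start_ms) / 1000 * fs))
}

# Start offset of the half-open window in samples (can be negative).
window_offset <- function(window, fs) as.integer(round(window$start_ms / 1000 * fs))
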