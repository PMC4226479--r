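#' Detect R peaks by matched filtering
#'
#' Finds R peaks in a single-channel ECG trace by normalized
#' cross-correlation against a short QRS template. Candidate peaks are
#' local maxima of the correlation trace above `threshold`, thinned by a
#' refractory period so no two peaks are closer than physiologically
#' plausible. This automates the semi-automatic template matching commonly
#' done in vendor software: pick one clean QRS complex, use it as the
#' template.
#'
#' @param ecg numeric vector, ECG in microvolts.
#' @param template numeric vector, a QRS waveform shorter than `ecg`.
#' @param fs sampling rate in Hz.
#' @param threshold minimal normalized cross-correlation in `[0, 1]`
#'   (default 0.7; a matched QRS template correlates near 1 at true
#'   beats and well below 0.7 elsewhere).
#' @param refractory_s refractory period in seconds (default 0.3,
#'   an upper bound on plausible heart rate).
#' @return An [rpeak_series] of template-aligned peak positions (position
#'   of the template maximum within each match).
#' @export
detect_r_peaks <- function(ecg, template, fs, threshold = 0.7, refractory_s = 0.3) {
  ecg <- as.numeric(ecg); template <- as.numeric(template)
  if (!all(is.finite(ecg))) stop("ecg contains non-finite samples")
  m <- length(template); n <- length(ecg)
  if (m >= n) stop("template must be shorter than ecg")
  if (stats::sd(ecg) == 0) stop("undetectable: ecg has zero variance")
  tc <- template - mean(template)
  tnorm <- sqrt(sum(tc^2))
  if (tnorm == 0) stop("template has zero variance")
  # sliding normalized cross-correlation via FFT convolution
  num <- fft_crosscorr(ecg, tc)                       # length n - m + 1
  csum <- c(0, cumsum(ecg)); csum2 <- c(0, cumsum(ecg^2))
  win_sum <- csum[(m + 1):(n + 1)] - csum[1:(n - m + 1)]
  win_sum2 <- csum2[(m + 1):(n + 1)] - csum2[1:(n - m + 1)]
  win_var <- pmax(win_sum2 - win_sum^2 / m, 0)
  ncc <- num / (tnorm * sqrt(win_var))
  ncc[win_var < .Machine$double.eps * m] <- 0
  # local maxima above threshold
  cand <- which(ncc >= threshold)
  cand <- cand[cand > 1 & cand < length(ncc)]
  cand <- cand[ncc[cand] >= ncc[cand - 1] & ncc[cand] >= ncc[cand + 1]]
  # refractory thinning: greedy by descending correlation
  refr <- as.integer(round(refractory_s * fs))
  keep <- integer(0)
  for (i in cand[order(ncc[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  if (!length(keep)) {
    warning("no R peaks found above threshold")
    return(structure(list(indices = integer(0), fs = fs), class = "rpeak_series"))
  }
  peaks <- sort(keep) + (which.max(template) - 1L)
  if (length(peaks) < 2L)
    return(structure(list(indices = as.integer(peaks), fs = fs), class = "rpeak_series"))
  rpeak_series(peaks, fs)
}

# cross-correlation of x with kernel k at lags 0..(n-m): sum(x[i:(i+m-1)] * k)
fft_crosscorr <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- stats::nextn(n + m, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  K <- stats::fft(c(rev(k), rep(0, nf - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nf
  full[m:n]
}

#' Cardiac-locked epoch set
#'
#' Segments a recording into fixed windows around each R peak. The window
#' is half-open `[start, end)` in samples after rounding the start offset,
#' so epoch length depends only on the window and sampling rate. Peaks
#' whose window does not fit fully inside the recording are dropped (never
#' zero-padded) and recorded in `kept`.
#'
#' @param rec an [eeg_recording].
#' @param rpeaks an [rpeak_series] with the same sampling rate.
#' @param window an [epoch_window].
#' @return An object of class `epoch_set`: a list with `epochs`
#'   (array epochs x channels x samples), `window`, `fs`, `labels`,
#'   `kept` (indices into `rpeaks$indices` of retained peaks).
#' @export
extract_epochs <- function(rec, rpeaks, window) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(rpeaks, "rpeak_series"),
            inherits(window, "epoch_window"))
  if (rpeaks$fs != rec$fs) stop("R-peak and recording sampling rates differ")
  ns <- window_samples(window, rec$fs)
  off <- window_offset(window, rec$fs)
  starts <- rpeaks$indices + off
  ok <- starts >= 1L & (starts + ns - 1L) <= n_samples(rec)
  kept <- which(ok)
  if (!length(kept)) stop("empty epoch set: no R-peak window fits the recording")
  arr <- array(0, dim = c(length(kept), n_channels(rec), ns))
  for (j in seq_along(kept)) {
    s <- starts[kept[j]]
    arr[j, , ] <- rec$data[, s:(s + ns - 1L), drop = FALSE]
  }
  structure(list(epochs = arr, window = window, fs = rec$fs,
                 labels = rec$labels, kept = kept,
                 rpeak_indices = rpeaks$indices[kept]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g..%g ms)\n",
              d[1], d[2], d[3], x$window$start_ms, x$window$end_ms))
  invisible(x)
}

#' Per-epoch sample ranges of a window within a recording
#'
#' @inheritParams extract_epochs
#' @return integer matrix with columns `start`, `end` (inclusive, 1-based),
#'   one row per retained R peak.
#' @export
epoch_ranges <- function(rec, rpeaks, window) {
  ns <- window_samples(window, rec$fs)
  off <- window_offset(window, rec$fs)
  starts <- rpeaks$indices + off
  ok <- starts >= 1L & (starts + ns - 1L) <= n_samples(rec)
  cbind(start = starts[ok], end = starts[ok] + ns - 1L)
}

#' Trim a recording to start at the n-th scanner volume marker
#'
#' MR-synchronized protocols discard the first few volumes; when scan
#' markers are available the recording (and any R-peak series) can be
#' trimmed to start at the `skip + 1`-th scan onset. Without markers
#' the whole input is used.
#'
#' @param rec an [eeg_recording].
#' @param markers data frame with `description` and `position` columns
#'   (as returned by [read_brainvision]).
#' @param pattern regular expression matching scan-onset marker
#'   descriptions (default `"Scan Start|R128"`, the common vendor tags).
#' @param skip number of initial scan volumes to drop (default 4, i.e.
#'   start from the fifth).
#' @param rpeaks optional [rpeak_series] shifted and filtered to the
#'   trimmed time base.
#' @return list with `recording` and (when given) `rpeaks`.
#' @export
trim_to_scan <- function(rec, markers, pattern = "Scan Start|R128",
                         skip = 4L, rpeaks = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  hits <- markers$position[grepl(pattern, markers$description)]
  if (length(hits) <= skip) stop("fewer than ", skip + 1L, " scan markers")
  start <- sort(hits)[skip + 1L]
  out <- eeg_recording(rec$data[, start:n_samples(rec), drop = FALSE],
                       rec$fs, rec$labels, stage = rec$stage, meta = rec$meta)
  res <- list(recording = out)
  if (!is.null(rpeaks)) {
    idx <- rpeaks$indices[rpeaks$indices >= start] - start + 1L
    res$rpeaks <- rpeak_series(idx, rpeaks$fs)
  }
  res
}

#' Partition 10-20 channel labels by hemisphere
#'
#' Follows the 10-20 convention: odd-numbered labels lie over the left
#' hemisphere, even-numbered over the right, and `z`-suffixed labels on
#' the midline ("mesial"). Mesial channels are later included in both
#' hemispheric pulse-artifact templates. The occipital subset (O1, O2,
#' Oz) drives the alpha-band quality metrics.
#'
#' @param labels character vector of 10-20 channel names.
#' @return An object of class `hemisphere_partition` with elements
#'   `left`, `right`, `mesial`, `occipital`.
#' @export
partition_channels <- function(labels) {
  if (!length(labels)) stop("labels must be non-empty")
  lab <- as.character(labels)
  letters_part <- sub("([0-9]+|z|Z)$", "", lab)
  sites <- c("Fp", "AF", "F", "FT", "FC", "T", "C", "TP", "CP", "P", "PO",
             "O", "I", "A", "M", "N")   # 10-20 / 10-10 site prefixes
  bad <- !grepl("^[A-Za-z]{1,4}([0-9]{1,2}|z|Z)$", lab) |
    !toupper(letters_part) %in% toupper(sites)
  if (any(bad))
    stop("unknown montage label(s): ", paste(lab[bad], collapse = ", "))
  num <- sub("^[A-Za-z]+", "", lab)
  mesial <- lab[grepl("(z|Z)$", lab)]
  digits <- suppressWarnings(as.integer(num[!grepl("(z|Z)$", lab)]))
  lateral <- lab[!grepl("(z|Z)$", lab)]
  left <- lateral[digits %% 2L == 1L]
  right <- lateral[digits %% 2L == 0L]
  occ <- intersect(c("O1", "O2", "Oz"), lab)
  structure(list(left = left, right = right, mesial = mesial, occipital = occ),
            class = "hemisphere_partition")
}

#' @export
print.hemisphere_partition <- function(x, ...) {
  cat(sprintf("<hemisphere_partition> left %d | right %d | mesial %d; occipital: %s\n",
              length(x$left), length(x$right), length(x$mesial),
              paste(x$occipital, collapse = " ")))
  invisible(x)
}
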