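#' Selection result
#'
#' Scores and removal decisions for all independent components under one
#' selection criterion.
#'
#' @param method one of `"pvaf"`, `"corr"`, `"pacf"`, `"wave"`.
#' @param scores numeric per-component scores.
#' @param mask logical per-component removal flags.
#' @param threshold_rule human-readable description of the rule applied.
#' @param params named list of the rule's parameters.
#' @return object of class `selection_result`.
#' @export
selection_result <- function(method, scores, mask, threshold_rule, params = list()) {
  stopifnot(length(scores) == length(mask), is.logical(mask))
  structure(list(method = method, scores = as.numeric(scores), mask = mask,
                 threshold_rule = threshold_rule, params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s: %d of %d components marked (%s)\n",
              x$method, sum(x$mask), length(x$mask), x$threshold_rule))
  invisible(x)
}

#' Variance-contribution (pvaf) criterion
#'
#' Back-projects each component to channel space and computes the
#' percentage of the reference signal's variance it explains within the
#' pulse-artifact intervals (all channels pooled). Components above the
#' threshold (default 2.5% of the initial variance) are marked for
#' removal.
#'
#' @param dec an `ica_decomposition`.
#' @param reference the recording the decomposition was fitted to (the
#'   post-OBS signal whose variance is "initial" here).
#' @param rpeaks an [rpeak_series].
#' @param pa_window pulse-artifact window (default 0--700 ms).
#' @param threshold_pct removal threshold in percent (default 2.5).
#' @return a [selection_result] with percent-variance scores.
#' @export
score_pvaf <- function(dec, reference, rpeaks, pa_window = epoch_window(0, 700),
                       threshold_pct = 2.5) {
  stopifnot(inherits(dec, "ica_decomposition"), inherits(reference, "eeg_recording"))
  rng <- epoch_ranges(reference, rpeaks, pa_window)
  idx <- unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]))
  ref_var <- sum(apply(reference$data[, idx, drop = FALSE], 1, stats::var))
  if (ref_var <= 0) stop("degenerate reference: zero variance in the PA intervals")
  k <- nrow(dec$sources)
  src_var <- apply(dec$sources[, idx, drop = FALSE], 1, stats::var)
  scores <- 100 * colSums(dec$mixing^2) * src_var / ref_var
  selection_result("pvaf", scores, scores > threshold_pct,
                   sprintf("score > %.3g%% of initial PA-interval variance", threshold_pct),
                   list(threshold_pct = threshold_pct))
}

#' Hemispheric pulse-artifact templates
#'
#' Averages the *uncorrected* (pre-OBS) signal over the pulse-artifact
#' epochs and over the channels of each hemisphere; midline ("mesial")
#' channels contribute to both templates. The artifact flips polarity
#' between hemispheres, so two templates are needed.
#'
#' @param rec_raw an [eeg_recording] with stage `"raw"`.
#' @param rpeaks an [rpeak_series].
#' @param part a `hemisphere_partition` of `rec_raw$labels`.
#' @param pa_window pulse-artifact window (default 0--700 ms).
#' @return object of class `pa_template_pair` with numeric `left`,
#'   `right` waveforms and the window.
#' @export
build_pa_templates <- function(rec_raw, rpeaks, part, pa_window = epoch_window(0, 700)) {
  stopifnot(inherits(rec_raw, "eeg_recording"))
  if (rec_raw$stage != "raw")
    stop("templates must use uncorrected signal (stage 'raw', got '", rec_raw$stage, "')")
  ep <- extract_epochs(rec_raw, rpeaks, pa_window)
  grand <- apply(ep$epochs, c(2, 3), mean)     # channels x samples
  rownames(grand) <- ep$labels
  lft <- c(part$left, part$mesial); rgt <- c(part$right, part$mesial)
  if (!length(lft) || !length(rgt)) stop("hemisphere groups are empty")
  structure(list(left = colMeans(grand[lft, , drop = FALSE]),
                 right = colMeans(grand[rgt, , drop = FALSE]),
                 window = pa_window, fs = rec_raw$fs, built_from = "raw"),
            class = "pa_template_pair")
}

# epoch-average a single source activation over a window
average_source_epochs <- function(src, rpeaks, window, fs) {
  ns <- window_samples(window, fs)
  off <- window_offset(window, fs)
  starts <- rpeaks$indices + off
  starts <- starts[starts >= 1L & (starts + ns - 1L) <= length(src)]
  if (!length(starts)) stop("empty epoch set for source averaging")
  acc <- numeric(ns)
  for (s in starts) acc <- acc + src[s:(s + ns - 1L)]
  acc / length(starts)
}

#' Template-correlation (corr) criterion
#'
#' Correlates each component's epoch-averaged activation with the two
#' hemispheric pulse-artifact templates. The score is the larger absolute
#' Pearson correlation; components scoring at least `rel_threshold`
#' (default 40%) of the maximum score are marked.
#'
#' @inheritParams score_pvaf
#' @param templates a `pa_template_pair` built from the raw signal.
#' @param rel_threshold relative threshold w.r.t. the maximum (default 0.4).
#' @return a [selection_result] with absolute-correlation scores.
#' @export
score_corr <- function(dec, templates, rpeaks, rel_threshold = 0.4) {
  stopifnot(inherits(dec, "ica_decomposition"), inherits(templates, "pa_template_pair"))
  k <- nrow(dec$sources)
  scores <- numeric(k)
  for (i in seq_len(k)) {
    avg <- average_source_epochs(dec$sources[i, ], rpeaks, templates$window, dec$fs)
    if (stats::sd(avg) == 0) {
      warning("component ", i, " has zero-variance epoch average; score 0")
      next
    }
    scores[i] <- max(abs(stats::cor(avg, templates$left)),
                     abs(stats::cor(avg, templates$right)))
  }
  thr <- rel_threshold * max(scores)
  selection_result("corr", scores, scores >= thr & scores > 0,
                   sprintf("score >= %.0f%% of the maximum correlation", 100 * rel_threshold),
                   list(rel_threshold = rel_threshold))
}

#' Partial-autocorrelation (pacf) criterion
#'
#' Averages consecutive non-overlapping blocks of `block_size`
#' pulse-artifact epochs (default 4) sample-wise within each block,
#' concatenates the block averages into one sequence, and computes its
#' partial autocorrelation function. A cardiac component recurs once
#' per heartbeat; in the concatenated epoch stream that recurrence sits
#' at a lag of one epoch length when the window is shorter than the R-R
#' interval (the inter-epoch gap is cut out), and at the mean R-R lag
#' otherwise. Averaging only a few epochs per block keeps enough
#' background in the sequence for the recurrence to appear as a genuine
#' PACF peak (a noise-free periodic sequence is finitely AR-predictable
#' and shows none). The score is the PACF value at a significant local
#' peak within `lag_tol` of the target lag (0 if none); components with
#' a peak scoring above `rel_threshold` (default 1/3) of the maximum
#' peak are marked.
#'
#' @inheritParams score_pvaf
#' @param block_size pulse-artifact epochs per block (default 4).
#' @param rel_threshold fraction of the maximum peak amplitude (default 1/3).
#' @param lag_tol half-width of the peak search window as a fraction of
#'   the target lag (default 0.1).
#' @return a [selection_result] with PACF peak-amplitude scores.
#' @export
score_pacf <- function(dec, rpeaks, pa_window = epoch_window(0, 700),
                       block_size = 4L, rel_threshold = 1/3, lag_tol = 0.1) {
  stopifnot(inherits(dec, "ica_decomposition"))
  ns <- window_samples(pa_window, dec$fs)
  off <- window_offset(pa_window, dec$fs)
  nsmp <- ncol(dec$sources)
  starts <- rpeaks$indices + off
  starts <- starts[starts >= 1L & (starts + ns - 1L) <= nsmp]
  n_blocks <- length(starts) %/% block_size
  if (n_blocks < 2L) stop("need at least 2 blocks of ", block_size, " PA epochs")
  series_len <- n_blocks * ns
  rr <- round(mean_rr_samples(rpeaks))
  target <- as.integer(min(rr, ns))       # cardiac recurrence lag in the stream
  lag_max <- as.integer(ceiling(target * (1 + 2 * lag_tol))) + 2L
  if (lag_max >= series_len) stop("block too short for R-R lag")
  lo <- max(2L, as.integer(floor(target * (1 - lag_tol))))
  hi <- as.integer(ceiling(target * (1 + lag_tol)))
  # conservative white-noise band: the peak is searched over ~target/5
  # lags, so the usual 2/sqrt(N) band would fire on noise alone
  sig_bound <- 4 / sqrt(series_len)
  k <- nrow(dec$sources)
  scores <- numeric(k); has_peak <- logical(k)
  for (i in seq_len(k)) {
    seq_avg <- numeric(series_len)
    for (b in seq_len(n_blocks)) {
      st <- starts[((b - 1L) * block_size + 1L):(b * block_size)]
      acc <- numeric(ns)
      for (s in st) acc <- acc + dec$sources[i, s:(s + ns - 1L)]
      seq_avg[((b - 1L) * ns + 1L):(b * ns)] <- acc / block_size
    }
    if (stats::sd(seq_avg) == 0) next
    p <- as.numeric(stats::pacf(seq_avg, lag.max = lag_max, plot = FALSE)$acf)
    # local maxima of the PACF curve inside the search window
    win <- lo:min(hi, lag_max - 1L)
    loc <- win[p[win] >= p[win - 1L] & p[win] >= p[win + 1L]]
    loc <- loc[p[loc] > sig_bound]
    if (length(loc)) {
      has_peak[i] <- TRUE
      scores[i] <- max(p[loc])
    }
  }
  thr <- rel_threshold * max(scores)
  mask <- has_peak & scores > thr & scores > 0
  selection_result("pacf", scores, mask,
                   sprintf("R-R-lag PACF peak > 1/3 of maximum (target lag %d samples)", target),
                   list(block_size = block_size, rel_threshold = rel_threshold,
                        target_lag = target, sig_bound = sig_bound))
}

#' Wavelet time-locking (wave) criterion
#'
#' For each component, computes the Morlet CWT magnitude on the
#' continuous activation, averages it over the pulse-artifact epochs,
#' and scores how time-locked the averaged map is: the peak of each
#' frequency row between the delta and alpha bands (1--13 Hz by
#' default), divided by that row's temporal median, maximized over rows.
#' A stationary rhythm averages to a flat row (score near 1); an
#' R-locked transient produces a localized bump (score well above 1).
#' Components scoring at or above `threshold` (default 3) are marked.
#' This automated score stands in for the visual inspection of component
#' time-frequency maps that it was designed to emulate.
#'
#' @inheritParams score_pvaf
#' @param freqs analysis grid (default [wave_freqs()]: 1--20 Hz, 20
#'   log-spaced rows).
#' @param band frequency band searched for time-locked peaks, in Hz
#'   (default `c(1, 13)`).
#' @param threshold peak-to-median ratio above which a component is
#'   marked (default 3).
#' @param q Morlet center-frequency/bandwidth ratio (default 2.5).
#' @return a [selection_result] with time-locking-ratio scores.
#' @export
score_wave <- function(dec, rpeaks, pa_window = epoch_window(0, 700),
                       freqs = wave_freqs(), band = c(1, 13),
                       threshold = 3, q = 2.5) {
  stopifnot(inherits(dec, "ica_decomposition"))
  rows <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(rows)) stop("band contains no analysis frequencies")
  k <- nrow(dec$sources)
  scores <- numeric(k)
  for (i in seq_len(k)) {
    src <- dec$sources[i, ]
    if (all(src == 0)) next
    mag <- cwt_morlet(src, dec$fs, freqs, q = q)
    map <- epoch_average_map(mag, rpeaks, pa_window, dec$fs)
    floor_mag <- 1e-4 * max(map)     # rows with no real energy score 0
    ratio <- apply(map[rows, , drop = FALSE], 1, function(r) {
      md <- stats::median(r)
      if (md <= floor_mag) 0 else max(r) / md
    })
    scores[i] <- max(ratio)
  }
  selection_result("wave", scores, scores >= threshold,
                   sprintf("time-locking ratio >= %.2g in %g-%g Hz", threshold, band[1], band[2]),
                   list(threshold = threshold, band = band, q = q))
}

#' Apply a selection result to a recording
#'
#' Removes the marked components (delegating to [remove_components])
#' and records the method, scores and count in the output metadata.
#'
#' @inheritParams remove_components
#' @param result a [selection_result] whose mask length equals the
#'   component count.
#' @return the corrected [eeg_recording], stage `"post_ica"`.
#' @export
apply_selection <- function(rec, dec, result) {
  stopifnot(inherits(result, "selection_result"))
  if (length(result$mask) != nrow(dec$sources))
    stop("selection mask length (", length(result$mask),
         ") does not match component count (", nrow(dec$sources), ")")
  remove_components(rec, dec, result$mask, method = result$method,
                    scores = result$scores)
}
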