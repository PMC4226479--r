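#' Frequency band definition
#'
#' @param delta,theta,alpha `[low, high]` pairs in Hz; must be ascending
#'   and non-overlapping. Defaults: delta 1--4, theta 4--8, alpha 8--13 Hz.
#' @return object of class `band_definition`.
#' @export
band_definition <- function(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13)) {
  b <- rbind(delta, theta, alpha)
  if (any(b[, 2] <= b[, 1])) stop("each band needs high > low")
  if (delta[2] > theta[1] || theta[2] > alpha[1])
    stop("bands must be non-overlapping and ascending")
  structure(list(delta = delta, theta = theta, alpha = alpha),
            class = "band_definition")
}

#' Peak-to-peak ratio
#'
#' For each channel, the mean over epochs of the within-epoch amplitude
#' range (max minus min), and the ratio of that quantity after versus
#' before ICA correction. The maximum signal excursion in a cardiac
#' epoch is dominated by the pulse artifact, so a smaller ratio means
#' more artifact removed.
#'
#' @param pre,post `epoch_set`s over the same window, channels and
#'   epochs (conventionally -200--1000 ms around the R peaks).
#' @return list with `per_channel` named ratio vector and `mean`.
#' @export
ptp_ratio <- function(pre, post) {
  stopifnot(inherits(pre, "epoch_set"), inherits(post, "epoch_set"))
  if (!identical(dim(pre$epochs), dim(post$epochs)))
    stop("pre/post epoch sets differ in shape")
  ptp <- function(es) {
    apply(es$epochs, c(1, 2), function(v) max(v) - min(v))  # epochs x channels
  }
  pre_m <- colMeans(ptp(pre)); post_m <- colMeans(ptp(post))
  ok <- pre_m > 0
  if (!all(ok)) warning("excluding ", sum(!ok), " channel(s) with zero pre peak-to-peak")
  ratio <- post_m[ok] / pre_m[ok]
  names(ratio) <- pre$labels[ok]
  list(per_channel = ratio, mean = mean(ratio))
}

#' Autoregressive (Burg) power spectral density
#'
#' Fits an AR model of the given order by Burg's method and evaluates
#' the one-sided parametric PSD on a frequency grid. An AR spectrum
#' resolves the alpha peak on short epochs where a periodogram cannot.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param order AR order (default 16; resolves alpha vs theta on 1.2 s
#'   epochs at 250 Hz).
#' @param freqs evaluation grid in Hz (default 0.5--30 Hz, 0.25 Hz step).
#' @return list with `freqs` and non-negative `psd` (power per Hz).
#' @export
ar_psd <- function(x, fs, order = 16L, freqs = seq(0.5, 30, by = 0.25)) {
  x <- as.numeric(x)
  if (order >= length(x)) stop("order must be below the signal length")
  if (stats::sd(x) == 0) stop("degenerate signal: zero variance")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  om <- outer(freqs / fs, seq_along(a), function(f, k) -2 * pi * f * k)
  denom <- Mod(1 - (cos(om) + 1i * sin(om)) %*% as.complex(a))^2
  list(freqs = freqs, psd = as.numeric(2 * fit$var.pred / (fs * denom)))
}

#' Mean AR PSD over epochs and channels
#'
#' Computes the Burg PSD of every epoch of every requested channel and
#' averages, the standard way to estimate a stable resting spectrum from
#' cardiac-locked validation epochs.
#'
#' @param rec an [eeg_recording].
#' @param rpeaks an [rpeak_series].
#' @param channels channel labels to include (e.g. the occipital set).
#' @param window epoch window (default -200--1000 ms).
#' @inheritParams ar_psd
#' @return list with `freqs` and `psd` (the epoch- and channel-mean).
#' @export
epoch_mean_psd <- function(rec, rpeaks, channels,
                           window = epoch_window(-200, 1000),
                           order = 16L, freqs = seq(0.5, 30, by = 0.25)) {
  if (!length(channels)) stop("empty channel subset")
  missing_ch <- setdiff(channels, rec$labels)
  if (length(missing_ch)) stop("unknown channels: ", paste(missing_ch, collapse = ", "))
  ep <- extract_epochs(rec, rpeaks, window)
  ci <- match(channels, ep$labels)
  acc <- numeric(length(freqs)); nn <- 0L
  for (e in seq_len(dim(ep$epochs)[1])) {
    for (c in ci) {
      x <- ep$epochs[e, c, ]
      if (stats::sd(x) == 0) next
      acc <- acc + ar_psd(x, rec$fs, order = order, freqs = freqs)$psd
      nn <- nn + 1L
    }
  }
  if (!nn) stop("degenerate signal: all epochs flat")
  list(freqs = freqs, psd = acc / nn)
}

# trapezoidal band power of a sampled PSD
band_power <- function(freqs, psd, band) {
  sel <- freqs >= band[1] & freqs <= band[2]
  if (sum(sel) < 2) stop("band contains fewer than 2 grid points")
  f <- freqs[sel]; p <- psd[sel]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Post/pre band-power ratios
#'
#' Integrates two PSDs over the delta, theta and alpha bands and returns
#' the post/pre power ratio per band, plus the ratio over the combined
#' delta+theta range (the band where the pulse artifact concentrates).
#'
#' @param psd_pre,psd_post lists with `freqs`/`psd` on the same grid.
#' @param bands a [band_definition].
#' @return named list: `delta_ratio`, `theta_ratio`, `alpha_ratio`,
#'   `delta_theta_ratio` (`NA` where the pre power is zero).
#' @export
band_ratios <- function(psd_pre, psd_post, bands = band_definition()) {
  if (!isTRUE(all.equal(psd_pre$freqs, psd_post$freqs)))
    stop("pre/post PSD grids differ")
  one <- function(band) {
    pre <- band_power(psd_pre$freqs, psd_pre$psd, band)
    post <- band_power(psd_post$freqs, psd_post$psd, band)
    if (pre <= 0) { warning("zero pre band power"); return(NA_real_) }
    post / pre
  }
  list(delta_ratio = one(bands$delta),
       theta_ratio = one(bands$theta),
       alpha_ratio = one(bands$alpha),
       delta_theta_ratio = one(c(bands$delta[1], bands$theta[2])))
}

#' Quality coefficient
#'
#' The alpha-band power ratio divided by the mean of the delta and theta
#' ratios. Proportional to the amount of low-frequency (artifact) power
#' cancelled and alpha (physiological) power preserved: higher is better.
#'
#' @param ratios list with `alpha_ratio`, `delta_ratio`, `theta_ratio`
#'   (as from [band_ratios]).
#' @return scalar QC.
#' @export
quality_coefficient <- function(ratios) {
  need <- c("alpha_ratio", "delta_ratio", "theta_ratio")
  if (any(!need %in% names(ratios)) || any(is.na(unlist(ratios[need]))))
    stop("all three band ratios must be present")
  denom <- (ratios$delta_ratio + ratios$theta_ratio) / 2
  if (denom <= 0) stop("degenerate QC: zero delta/theta denominator")
  ratios$alpha_ratio / denom
}

#' Epoch-mean CWT magnitude map of a channel subset
#'
#' Computes the Morlet CWT magnitude of each channel's continuous
#' signal, averages it over the validation epochs and over the channel
#' subset. The map separates continuous (physiological) from R-locked
#' (artifactual) spectral content.
#'
#' @inheritParams epoch_mean_psd
#' @param freqs analysis grid (default [tfc_freqs()]).
#' @param q Morlet center-frequency/bandwidth ratio (default 2.5).
#' @return matrix freqs x samples with attributes `freqs`, `fs`,
#'   `window`.
#' @export
cwt_epoch_mean <- function(rec, rpeaks, channels,
                           window = epoch_window(-200, 1000),
                           freqs = tfc_freqs(), q = 2.5) {
  if (!length(channels)) stop("empty channel subset")
  missing_ch <- setdiff(channels, rec$labels)
  if (length(missing_ch)) stop("unknown channels: ", paste(missing_ch, collapse = ", "))
  acc <- NULL
  for (ch in channels) {
    mag <- cwt_morlet(rec$data[match(ch, rec$labels), ], rec$fs, freqs, q = q)
    map <- epoch_average_map(mag, rpeaks, window, rec$fs)
    acc <- if (is.null(acc)) map else acc + map
  }
  out <- acc / length(channels)
  attr(out, "freqs") <- freqs
  attr(out, "fs") <- rec$fs
  attr(out, "window") <- window
  out
}

#' Removed time-frequency content and its mean time derivative
#'
#' `cwt_off()` is the signed difference between the epoch-mean CWT maps
#' before and after correction: the time-frequency content the
#' correction removed. `mean_time_derivative()` summarizes how
#' time-locked that removed content is: the mean over frequency rows of
#' the mean absolute finite difference along time, in magnitude units
#' per second. Removal of R-locked content yields a large value;
#' removal of a stationary rhythm (constant rows) yields zero.
#'
#' @param cwt_pre,cwt_post maps from [cwt_epoch_mean] on identical grids.
#' @return `cwt_off`: the difference map (same attributes).
#' @export
cwt_off <- function(cwt_pre, cwt_post) {
  if (!identical(dim(cwt_pre), dim(cwt_post)) ||
      !isTRUE(all.equal(attr(cwt_pre, "freqs"), attr(cwt_post, "freqs"))))
    stop("pre/post CWT grids differ")
  out <- cwt_pre - cwt_post
  attributes(out) <- attributes(cwt_pre)
  out
}

#' @rdname cwt_off
#' @param map a CWT map (freqs x samples) with an `fs` attribute, or a
#'   plain matrix plus explicit `fs`.
#' @param fs sampling rate in Hz (taken from the map's attribute when
#'   present).
#' @return `mean_time_derivative`: scalar MD >= 0.
#' @export
mean_time_derivative <- function(map, fs = attr(map, "fs")) {
  if (is.null(fs)) stop("fs required")
  d <- abs(t(diff(t(map)))) * fs      # |d/dt| per row, magnitude units / s
  mean(rowMeans(d))
}

#' Nonparametric comparison of correction methods
#'
#' Kruskal-Wallis omnibus test across method groups of per-subject
#' metric values; when the omnibus test is significant, Tukey-style
#' pairwise comparisons on mean ranks (Nemenyi procedure, tie-corrected)
#' flag which method pairs differ.
#'
#' @param groups named list of numeric vectors (one per method), each of
#'   length >= 2.
#' @param alpha significance level (default 0.05).
#' @return list with `p_omnibus`, `statistic`, and `pairwise` (data
#'   frame with columns `group1`, `group2`, `p`, `significant`; empty
#'   when the omnibus test is not significant).
#' @export
compare_methods <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  p <- kw$p.value
  if (is.nan(p)) p <- 1   # all observations tied
  pairwise <- data.frame(group1 = character(0), group2 = character(0),
                         p = numeric(0), significant = logical(0))
  if (p < alpha) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(names(groups), vapply(groups, length, 1L))
    r <- rank(x)
    N <- length(x); k <- length(groups)
    ties <- table(x)
    tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    mean_r <- tapply(r, g, mean)[names(groups)]
    n_i <- vapply(groups, length, 1L)
    combs <- utils::combn(names(groups), 2)
    pw <- apply(combs, 2, function(pair) {
      i <- pair[1]; j <- pair[2]
      se <- sqrt(N * (N + 1) / 12 * tie_corr * (1 / n_i[i] + 1 / n_i[j]))
      q <- abs(mean_r[i] - mean_r[j]) / se * sqrt(2)
      1 - stats::ptukey(q, k, Inf)
    })
    pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                           p = as.numeric(pw), significant = pw < alpha)
  }
  list(p_omnibus = p, statistic = unname(kw$statistic), pairwise = pairwise)
}

#' Full quality report for one correction
#'
#' Runs all three validation families on a pre/post recording pair:
#' peak-to-peak ratios (all channels), AR band-power ratios and the
#' quality coefficient (occipital channels), and the mean time
#' derivative of the removed time-frequency content (all channels and
#' occipital subset).
#'
#' @param pre recording before ICA correction (post-OBS).
#' @param post recording after component removal.
#' @param rpeaks an [rpeak_series].
#' @param window validation window (default -200--1000 ms).
#' @param bands a [band_definition].
#' @param ar_order Burg AR order (default 16).
#' @param tfc_q Morlet ratio for the time-frequency maps.
#' @param method optional method label stored in the report.
#' @return object of class `quality_report`.
#' @export
quality_report <- function(pre, post, rpeaks, window = epoch_window(-200, 1000),
                           bands = band_definition(), ar_order = 16L,
                           tfc_q = 2.5, method = NULL) {
  part <- partition_channels(pre$labels)
  occ <- part$occipital
  if (!length(occ)) stop("no occipital channels (O1/O2/Oz) in the montage")
  ep_pre <- extract_epochs(pre, rpeaks, window)
  ep_post <- extract_epochs(post, rpeaks, window)
  ptp <- ptp_ratio(ep_pre, ep_post)
  psd_pre <- epoch_mean_psd(pre, rpeaks, occ, window, order = ar_order)
  psd_post <- epoch_mean_psd(post, rpeaks, occ, window, order = ar_order)
  ratios <- band_ratios(psd_pre, psd_post, bands)
  qc <- tryCatch(quality_coefficient(ratios), error = function(e) NA_real_)
  md_of <- function(chs) {
    off <- cwt_off(cwt_epoch_mean(pre, rpeaks, chs, window, q = tfc_q),
                   cwt_epoch_mean(post, rpeaks, chs, window, q = tfc_q))
    mean_time_derivative(off)
  }
  structure(list(method = method,
                 ptp_ratio = ptp$per_channel, ptp_ratio_mean = ptp$mean,
                 delta_ratio = ratios$delta_ratio, theta_ratio = ratios$theta_ratio,
                 alpha_ratio = ratios$alpha_ratio,
                 delta_theta_ratio = ratios$delta_theta_ratio,
                 qc = qc,
                 cwt_md_all = md_of(pre$labels), cwt_md_occ = md_of(occ),
                 window = window, bands = bands),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report>%s\n", if (is.null(x$method)) "" else paste0(" method=", x$method)))
  cat(sprintf("  PTP ratio (mean)     %.4f\n", x$ptp_ratio_mean))
  cat(sprintf("  delta/theta/alpha    %.4f / %.4f / %.4f (d+t %.4f)\n",
              x$delta_ratio, x$theta_ratio, x$alpha_ratio, x$delta_theta_ratio))
  cat(sprintf("  QC                   %.4f\n", x$qc))
  cat(sprintf("  MD(CWT_off) all/occ  %.5g / %.5g\n", x$cwt_md_all, x$cwt_md_occ))
  invisible(x)
}

#' Serialize a quality report
#'
#' @param report a `quality_report`.
#' @param json_path,tsv_path output file paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_quality_report <- function(report, json_path = NULL, tsv_path = NULL) {
  scalars <- report[c("method", "ptp_ratio_mean", "delta_ratio", "theta_ratio",
                      "alpha_ratio", "delta_theta_ratio", "qc",
                      "cwt_md_all", "cwt_md_occ")]
  if (!is.null(json_path)) {
    payload <- c(scalars, list(ptp_ratio_per_channel = as.list(report$ptp_ratio)))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    num <- scalars[-1]
    df <- data.frame(method = if (is.null(report$method)) NA else report$method,
                     metric = names(num), value = unlist(num, use.names = FALSE))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
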