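test_that("ptp_ratio identity, scaling, and ground-truth value", {
  ds <- tiny_dataset(1)
  w <- epoch_window(-200, 1000)
  pre <- extract_epochs(ds$mixed, ds$rpeaks, w)
  expect_equal(ptp_ratio(pre, pre)$per_channel,
               setNames(rep(1, 12), ds$mixed$labels))
  half <- pre; half$epochs <- pre$epochs * 0.5
  expect_equal(unname(ptp_ratio(pre, half)$mean), 0.5)
  # oracle from the generator's parts: pre = clean + artifact, post = clean
  post <- extract_epochs(ds$clean, ds$rpeaks, w)
  r <- ptp_ratio(pre, post)
  oracle <- sapply(seq_len(12), function(c) {
    mean(apply(post$epochs[, c, ], 1, function(v) max(v) - min(v))) /
      mean(apply(pre$epochs[, c, ], 1, function(v) max(v) - min(v)))
  })
  expect_equal(unname(r$per_channel), oracle, tolerance = 1e-12)
  expect_lt(r$mean, 1)    # removing the artifact shrinks the excursion
  # zero pre-excursion channels are excluded with a warning
  flat <- pre; flat$epochs[, 1, ] <- 0
  expect_warning(r2 <- ptp_ratio(flat, flat), "zero pre peak-to-peak")
  expect_length(r2$per_channel, 11L)
})

test_that("ar_psd locates spectral lines and rejects degenerate input", {
  set.seed(12)
  fs <- 250; n <- 300
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10 * t) + rnorm(n, 0, 0.05)
  p <- ar_psd(x, fs, order = 16)
  expect_equal(p$freqs[which.max(p$psd)], 10, tolerance = 0.05)
  expect_true(all(p$psd >= 0))
  # white noise is much flatter over 1-20 Hz than the sinusoid case
  dyn <- function(psd) {
    sel <- psd$freqs >= 1 & psd$freqs <= 20
    max(psd$psd[sel]) / min(psd$psd[sel])
  }
  wn <- ar_psd(rnorm(n), fs, order = 16)
  expect_gt(dyn(p) / dyn(wn), 10)
  expect_error(ar_psd(rep(0, n), fs), "degenerate")
  expect_error(ar_psd(x[1:10], fs, order = 16), "order")
})

test_that("band powers integrate exactly for a boxcar PSD", {
  freqs <- seq(0.5, 30, by = 0.25)
  boxcar <- ifelse(freqs >= 4 & freqs <= 8, 2, 0)
  pre <- list(freqs = freqs, psd = rep(1, length(freqs)))
  post <- list(freqs = freqs, psd = boxcar)
  r <- band_ratios(pre, post)
  # closed-form trapezoid integrals of the piecewise-linear boxcar:
  # theta post = 2*(8-4) = 8 over pre = 4; the neighboring bands see only
  # the half-step triangle (0+2)/2 * 0.25 at the shared edge
  expect_equal(r$theta_ratio, 2)
  expect_equal(r$alpha_ratio, 0.25 / 5)
  expect_equal(r$delta_ratio, 0.25 / 3)
  expect_equal(band_ratios(pre, pre)[["alpha_ratio"]], 1)
  zero <- list(freqs = freqs, psd = rep(0, length(freqs)))
  w <- capture_warnings(rz <- band_ratios(zero, pre))   # one per band
  expect_true(all(grepl("zero pre band power", w)))
  expect_true(is.na(rz$delta_ratio))
})

test_that("quality coefficient arithmetic", {
  expect_equal(quality_coefficient(list(alpha_ratio = 0.6, delta_ratio = 0.5,
                                        theta_ratio = 0.4)),
               0.6 / 0.45, tolerance = 1e-12)   # 1.3333
  expect_equal(quality_coefficient(list(alpha_ratio = 1, delta_ratio = 0.5,
                                        theta_ratio = 0.5)), 2)
  expect_equal(quality_coefficient(list(alpha_ratio = .7, delta_ratio = .7,
                                        theta_ratio = .7)), 1)
  expect_error(quality_coefficient(list(alpha_ratio = 1, delta_ratio = 0,
                                        theta_ratio = 0)), "degenerate QC")
  expect_error(quality_coefficient(list(alpha_ratio = 1)), "present")
})

test_that("band_definition validates ordering", {
  b <- band_definition()
  expect_equal(b$delta, c(1, 4))
  expect_equal(b$alpha, c(8, 13))
  expect_error(band_definition(delta = c(1, 5), theta = c(4, 8)),
               "non-overlapping")
  expect_error(band_definition(delta = c(4, 1)), "high > low")
})

test_that("cwt_epoch_mean: stationary rows flat, locked bursts peak, zero in zero out", {
  fs <- 250; n <- 30000
  set.seed(13)
  rp <- periodic_rpeaks(110, 250, fs)
  t <- (0:(n - 1)) / fs
  sine <- matrix(sin(2 * pi * 10 * t), 1)
  rec_sine <- eeg_recording(sine, fs, "Oz")
  map <- cwt_epoch_mean(rec_sine, rp, "Oz")
  f10 <- which.min(abs(tfc_freqs() - 10))
  row <- map[f10, ]
  expect_lt((max(row) - min(row)) / mean(row), 0.05)
  # R-locked 6 Hz burst peaks at its latency above twice its own median
  x <- numeric(n)
  burst <- sin(2 * pi * 6 * seq(0, 0.149, by = 1 / fs))
  for (p in rp$indices) {
    s <- p + round(0.25 * fs)
    if (s + 37 <= n) x[s:(s + 37)] <- x[s:(s + 37)] + burst
  }
  map2 <- cwt_epoch_mean(eeg_recording(matrix(x, 1), fs, "Oz"), rp, "Oz")
  f6 <- which.min(abs(tfc_freqs() - 6))
  expect_gt(max(map2[f6, ]), 2 * median(map2[f6, ]))
  zero <- eeg_recording(matrix(0, 1, n), fs, "Oz")
  expect_equal(max(abs(cwt_epoch_mean(zero, rp, "Oz"))), 0)
  expect_error(cwt_epoch_mean(rec_sine, rp, character(0)), "empty channel")
})

test_that("cwt_off and the mean time derivative behave as a lock detector", {
  fs <- 250; n <- 30000
  set.seed(14)
  rp <- periodic_rpeaks(110, 250, fs)
  base <- eeg_recording(matrix(pacorrect:::pink_noise(n) * 5, 1), fs, "Oz")
  map <- cwt_epoch_mean(base, rp, "Oz")
  expect_equal(mean_time_derivative(cwt_off(map, map)), 0)
  const <- map; const[] <- 3
  attr(const, "fs") <- fs
  expect_equal(mean_time_derivative(const), 0)
  expect_error(cwt_off(map, map[, 1:10]), "grids differ")
  # removal of an R-locked burst vs an equal-energy continuous sinusoid
  burst_sig <- numeric(n)
  burst <- 8 * sin(2 * pi * 6 * seq(0, 0.149, by = 1 / fs))
  for (p in rp$indices) {
    s <- p + round(0.25 * fs)
    if (s + 37 <= n) burst_sig[s:(s + 37)] <- burst_sig[s:(s + 37)] + burst
  }
  alpha_sig <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  alpha_sig <- alpha_sig * sqrt(sum(burst_sig^2) / sum(alpha_sig^2))
  pre <- eeg_recording(base$data + rbind(burst_sig) + rbind(alpha_sig), fs, "Oz")
  post_lock <- eeg_recording(pre$data - rbind(burst_sig), fs, "Oz")
  post_cont <- eeg_recording(pre$data - rbind(alpha_sig), fs, "Oz")
  map_pre <- cwt_epoch_mean(pre, rp, "Oz")
  md_lock <- mean_time_derivative(cwt_off(map_pre, cwt_epoch_mean(post_lock, rp, "Oz")))
  md_cont <- mean_time_derivative(cwt_off(map_pre, cwt_epoch_mean(post_cont, rp, "Oz")))
  expect_gt(md_lock, md_cont)
})

test_that("compare_methods omnibus and pairwise behavior", {
  # identical groups: omnibus not significant, no pairwise flags
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  r <- compare_methods(g)
  expect_equal(r$p_omnibus, 1, tolerance = 1e-6)
  expect_equal(nrow(r$pairwise), 0L)
  # a clearly shifted group: only its pairs flagged
  g3 <- list(a = 1:5, b = 11:15, c = 1:5 + 0.01)
  r3 <- compare_methods(g3)
  expect_lt(r3$p_omnibus, 0.05)
  flagged <- r3$pairwise[r3$pairwise$significant, c("group1", "group2")]
  expect_true(all(apply(flagged, 1, function(p) "b" %in% p)))
  expect_false(any(flagged$group1 == "a" & flagged$group2 == "c"))
  # oracle: the tie-corrected KW statistic computed from first principles
  x <- unlist(g3); grp <- rep(names(g3), each = 5)
  rk <- rank(x); N <- length(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(rk, grp, function(r) length(r) *
        (mean(r) - (N + 1) / 2)^2))
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(r3$statistic, H, tolerance = 1e-10)
  expect_error(compare_methods(list(a = 1:5)), "at least 2 groups")
  expect_error(compare_methods(list(a = 1:5, b = 2)), ">= 2 values")
})

test_that("metrics are channel-order invariant and ratios scale correctly", {
  ds <- tiny_dataset(1)
  w <- epoch_window(-200, 1000)
  pre <- extract_epochs(ds$mixed, ds$rpeaks, w)
  post <- extract_epochs(ds$clean, ds$rpeaks, w)
  r1 <- ptp_ratio(pre, post)
  perm <- sample(1:12)
  rec_p <- eeg_recording(ds$mixed$data[perm, ], 250, ds$mixed$labels[perm])
  rec_c <- eeg_recording(ds$clean$data[perm, ], 250, ds$clean$labels[perm])
  r2 <- ptp_ratio(extract_epochs(rec_p, ds$rpeaks, w),
                  extract_epochs(rec_c, ds$rpeaks, w))
  expect_equal(r2$per_channel[ds$mixed$labels], r1$per_channel)
  expect_equal(r2$mean, r1$mean)
  # scaling post by c scales PTP ratio by c and band powers by c^2
  sc <- post; sc$epochs <- post$epochs * 3
  expect_equal(ptp_ratio(pre, sc)$mean, 3 * r1$mean)
  f <- seq(0.5, 30, 0.25)
  p1 <- list(freqs = f, psd = runif(length(f)) + 1)
  p2 <- list(freqs = f, psd = 9 * p1$psd)   # amplitude x3 = power x9
  expect_equal(band_ratios(p1, p2)$alpha_ratio, 9)
})
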