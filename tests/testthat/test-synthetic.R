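test_that("generate_rr: determinism, periodic limit, count statistics", {
  cfg <- tiny_config(7)
  rp1 <- generate_rr(cfg)
  rp2 <- generate_rr(cfg)
  expect_identical(rp1$indices, rp2$indices)
  expect_false(identical(generate_rr(tiny_config(8))$indices, rp1$indices))
  # rr_sd = 0: exactly periodic at rr_mean spacing
  rp0 <- generate_rr(tiny_config(1, rr_sd = 0))
  expect_equal(unique(diff(rp0$indices)), 250L)
  # count statistics over a long recording
  cfg_long <- synth_config(n_channels = 4, duration = 360, rr_sd = 0.05,
                           seed = 2, alpha_channels = c("F3", "F4"))
  rp <- generate_rr(cfg_long)
  expected <- (360 - 1.3) / 1.0
  expect_lt(abs(length(rp$indices) - expected), 3 * 0.05 * sqrt(360) + 2)
  expect_error(generate_rr(tiny_config(1, duration = 1)), "too short")
})

test_that("generate_artifact: gain 0, hemispheric antisymmetry, drift", {
  cfg <- tiny_config(3)
  rp <- generate_rr(cfg)
  z <- generate_artifact(rp, tiny_config(3, artifact_gain = 0))
  expect_equal(max(abs(z$recording$data)), 0)
  art <- generate_artifact(rp, cfg)
  part <- partition_channels(cfg$montage)
  ep <- extract_epochs(art$recording, rp, epoch_window(0, 700))
  grand <- apply(ep$epochs, c(2, 3), mean)
  rownames(grand) <- cfg$montage
  left_mean <- colMeans(grand[part$left, ])
  right_mean <- colMeans(grand[part$right, ])
  # polarity flips between hemispheres: strong anticorrelation
  expect_lt(cor(left_mean, right_mean), -0.95)
  # configured epoch-SNR calibration: artifact RMS ~ gain * background RMS
  rng <- epoch_ranges(art$recording, rp, epoch_window(0, 700))
  idx <- unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]))
  expect_equal(sqrt(mean(art$recording$data[, idx]^2)),
               cfg$artifact_gain * cfg$background_rms, tolerance = 1e-6)
})

test_that("artifact amplitude drift matches the configured modulation", {
  cfg <- tiny_config(5, duration = 240, artifact_drift = 0.5,
                     latency_jitter_ms = 0)
  rp <- generate_rr(cfg)
  art <- generate_artifact(rp, cfg)
  ep <- extract_epochs(art$recording, rp, epoch_window(0, 700))
  rms <- sqrt(apply(ep$epochs^2, 1, mean))
  nq <- floor(length(rms) / 4)
  measured <- mean(rms[(length(rms) - nq + 1):length(rms)]) / mean(rms[1:nq])
  # oracle from the generator's own drift law: 1 - drift*cos(pi*t/T)
  tt <- rp$indices[ep$kept] / cfg$fs
  gain <- 1 - cfg$artifact_drift * cos(pi * tt / cfg$duration)
  oracle <- mean(gain[(length(gain) - nq + 1):length(gain)]) / mean(gain[1:nq])
  expect_equal(measured, oracle, tolerance = 0.05)
})

test_that("generate_background: alpha where configured, 1/f elsewhere", {
  cfg <- tiny_config(4, duration = 120)
  bg <- generate_background(cfg)
  rp <- generate_rr(cfg)
  p_alpha <- epoch_mean_psd(bg, rp, "O1", order = 16L)
  sel <- p_alpha$freqs >= 5 & p_alpha$freqs <= 15
  peak_f <- p_alpha$freqs[sel][which.max(p_alpha$psd[sel])]
  expect_lt(abs(peak_f - cfg$alpha_freq), 0.5)
  # a non-alpha channel has no comparable alpha prominence
  p_flat <- epoch_mean_psd(bg, rp, "F3", order = 16L)
  prominence <- function(p) {
    a <- p$freqs >= 8 & p$freqs <= 13
    lo <- p$freqs >= 4 & p$freqs < 8
    max(p$psd[a]) / mean(p$psd[lo])
  }
  expect_gt(prominence(p_alpha), 1.5 * prominence(p_flat))
  expect_error(generate_background(tiny_config(1, duration = 0.001)),
               "zero-duration|too short|positive")
})

test_that("generate_dataset: additivity, determinism, seed sensitivity", {
  ds <- tiny_dataset(1)
  expect_equal(ds$mixed$data, ds$clean$data + ds$artifact$data)
  ds_b <- generate_dataset(tiny_config(1))
  expect_identical(ds$mixed$data, ds_b$mixed$data)
  ds2 <- generate_dataset(tiny_config(2))
  expect_gt(max(abs(ds2$mixed$data - ds$mixed$data)), 0)
  # artifact variance share in the PA windows matches the oracle projection
  rng <- epoch_ranges(ds$mixed, ds$rpeaks, epoch_window(0, 700))
  idx <- unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]))
  share <- sum(ds$artifact$data[, idx]^2) / sum(ds$clean$data[, idx]^2)
  cfg <- ds$config
  # oracle: artifact in-window power is calibrated to (gain*bg_rms)^2; the
  # clean power is bg_rms^2 plus the alpha power alpha_rms^2 * E[U(0.7,1)^2]
  # on the alpha channels (E[U(0.7,1)^2] = (1 - 0.7^3) / 0.9 = 0.73)
  expected <- cfg$artifact_gain^2 * cfg$background_rms^2 /
    (cfg$background_rms^2 +
       cfg$alpha_rms^2 * 0.73 * length(cfg$alpha_channels) / cfg$n_channels)
  expect_equal(share, expected, tolerance = 0.10)
  # the ECG trace is usable for detection: recovers the ground-truth peaks
  rp <- detect_r_peaks(ds$ecg, qrs_template(250), 250)
  expect_equal(length(rp$indices), length(ds$rpeaks$indices))
  expect_true(all(abs(rp$indices - ds$rpeaks$indices) <= 1))
})

test_that("synthetic_decomposition exposes ground truth", {
  cfg <- tiny_config(2, duration = 120)
  sd_ <- synthetic_decomposition(cfg, n_artifact = 3L, n_neural = 3L)
  expect_equal(sd_$truth, rep(c(TRUE, FALSE), each = 3))
  expect_equal(dim(sd_$dec$mixing), c(12L, 6L))
  # unmixing is a left inverse of mixing
  expect_equal(sd_$dec$unmixing %*% sd_$dec$mixing, diag(6), tolerance = 1e-8)
  # artifact sources are R-locked: epoch-averaged energy dominates
  s1 <- sd_$dec$sources[1, ]
  avg <- pacorrect:::average_source_epochs(s1, sd_$rpeaks, epoch_window(0, 700), 250)
  expect_gt(sqrt(mean(avg^2)), 0.5 * sd(s1))
})
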