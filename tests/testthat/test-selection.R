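# A 3-source constructed decomposition with known PA-interval variances.
three_source_fixture <- function(seed = 4, n = 15000, fs = 250) {
  set.seed(seed)
  rp <- periodic_rpeaks(55, 260, fs)
  k <- pacorrect:::pa_kernel(fs)
  train <- numeric(n)
  for (p in rp$indices) train[p:(p + length(k) - 1)] <- train[p:(p + length(k) - 1)] + k
  t <- (0:(n - 1)) / fs
  S <- rbind(3 * train / sd(train),
             sin(2 * pi * 10 * t + 2.1),
             rnorm(n))
  A <- matrix(c(1, .6, -.4, .2, 1, .5, -.3, .1, 1), 3, 3)
  dec <- manual_decomposition(S, A, fs)
  ref <- eeg_recording(A %*% S, fs, dec$labels, stage = "post_obs")
  list(dec = dec, ref = ref, rpeaks = rp, S = S, A = A)
}

test_that("pvaf scores equal the brute-force variance ratio", {
  fx <- three_source_fixture()
  sel <- score_pvaf(fx$dec, fx$ref, fx$rpeaks)
  # oracle: explicit back-projection, channel-wise variances over PA samples
  rng <- epoch_ranges(fx$ref, fx$rpeaks, epoch_window(0, 700))
  idx <- unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]))
  ref_var <- sum(apply(fx$ref$data[, idx], 1, var))
  oracle <- sapply(1:3, function(k) {
    bp <- outer(fx$A[, k], fx$S[k, idx])
    100 * sum(apply(bp, 1, var)) / ref_var
  })
  expect_equal(sel$scores, oracle, tolerance = 1e-10)
})

test_that("pvaf threshold rule and degenerate cases", {
  fx <- three_source_fixture()
  # threshold semantics on frozen scores: {3.0, 2.4} at 2.5% -> {TRUE, FALSE}
  sel <- selection_result("pvaf", c(3.0, 2.4), c(3.0, 2.4) > 2.5, "spec")
  expect_equal(sel$mask, c(TRUE, FALSE))
  # an all-zero source scores 0 and is never selected
  S0 <- fx$S; S0[2, ] <- 0
  dec0 <- manual_decomposition(S0, fx$A)
  sel0 <- score_pvaf(dec0, fx$ref, fx$rpeaks)
  expect_equal(sel0$scores[2], 0)
  expect_false(sel0$mask[2])
  zero_ref <- eeg_recording(matrix(0, 3, 15000), 250, fx$ref$labels,
                            stage = "post_obs")
  expect_error(score_pvaf(fx$dec, zero_ref, fx$rpeaks), "degenerate reference")
})

test_that("hemispheric templates average the raw signal with mesial in both", {
  fs <- 250
  rp <- periodic_rpeaks(10, 300, fs)
  w <- sin(2 * pi * 3 * seq(0, 0.699, by = 1 / fs))
  n <- 3200
  data <- matrix(0, 5, n)
  labels <- c("C3", "P3", "C4", "P4", "Cz")   # 2 left, 2 right, 1 mesial
  for (p in rp$indices) {
    data[1:2, p:(p + 174)] <- data[1:2, p:(p + 174)] + rep(w, each = 2)
    data[3:4, p:(p + 174)] <- data[3:4, p:(p + 174)] - rep(w, each = 2)
  }
  rec <- eeg_recording(data, fs, labels)
  part <- partition_channels(labels)
  tp <- build_pa_templates(rec, rp, part)
  expect_equal(tp$left, w * 2 / 3, tolerance = 1e-12)    # (+w+w+0)/3
  expect_equal(tp$right, -w * 2 / 3, tolerance = 1e-12)
  post <- eeg_recording(data, fs, labels, stage = "post_obs")
  expect_error(build_pa_templates(post, rp, part), "uncorrected")
})

test_that("corr scores identity, orthogonality and the relative threshold", {
  fs <- 250
  fx <- three_source_fixture()
  part <- partition_channels(pa_montage(6))
  raw <- generate_background(tiny_config(3, n_channels = 6, duration = 60, alpha_channels = c("C3", "C4")))
  rp <- generate_rr(tiny_config(3, n_channels = 6, duration = 60, alpha_channels = c("C3", "C4")))
  tmpl <- build_pa_templates(raw, rp, part)
  # source whose epoch average equals the left template scores 1
  n <- n_samples(raw)
  src_l <- numeric(n)
  for (p in rp$indices) {
    e <- p + 174L
    if (e <= n) src_l[p:e] <- src_l[p:e] + tmpl$left
  }
  # source orthogonal to both templates and the constant (Gram-Schmidt
  # against an orthonormalized basis, so all three stay orthogonal)
  set.seed(1)
  Q <- qr.Q(qr(cbind(rep(1, 175), tmpl$left, tmpl$right)))
  v <- rnorm(175)
  v <- v - Q %*% crossprod(Q, v)
  v <- as.numeric(v)
  src_o <- numeric(n)
  for (p in rp$indices) {
    e <- p + 174L
    if (e <= n) src_o[p:e] <- src_o[p:e] + v
  }
  dec <- manual_decomposition(rbind(src_l, src_o, rnorm(n) * 1e-2),
                              diag(3), fs, labels = c("C1", "C2", "C3"))
  sel <- score_corr(dec, tmpl, rp)
  expect_equal(sel$scores[1], 1, tolerance = 1e-6)
  expect_true(sel$mask[1])
  expect_lt(sel$scores[2], 0.05)
  # relative threshold semantics: {0.80, 0.33, 0.31} at 40% of max
  m <- selection_result("corr", c(.80, .33, .31),
                        c(.80, .33, .31) >= 0.4 * 0.80, "spec")
  expect_equal(m$mask, c(TRUE, TRUE, FALSE))
})

test_that("pacf flags periodic sources and ignores white noise", {
  fs <- 250
  set.seed(21)
  n <- 40000
  rp <- periodic_rpeaks(150, 250, fs)
  # strictly R-R periodic broadband waveform plus white noise at SNR 10
  w <- rnorm(250)
  period_sig <- rep(w, length.out = n)
  period_sig <- period_sig + rnorm(n, 0, sd(period_sig) / sqrt(10))
  S <- rbind(period_sig, rnorm(n))
  dec <- manual_decomposition(S, diag(2), fs, labels = c("C1", "C2"))
  sel <- score_pacf(dec, rp)
  expect_true(sel$mask[1])
  expect_false(sel$mask[2])
  expect_gt(sel$scores[1], sel$params$sig_bound)
  # relative threshold semantics: {0.9, 0.31, 0.29} vs max/3 = 0.30
  sc <- c(0.9, 0.31, 0.29)
  expect_equal(sc > max(sc) / 3, c(TRUE, TRUE, FALSE))
  # too few epochs to form two blocks
  rp_short <- rpeak_series(c(1L, 251L, 501L), fs)
  expect_error(score_pacf(dec, rp_short), "at least 2 blocks")
})

test_that("wave scores separate R-locked bursts from stationary rhythms", {
  fs <- 250; n <- 60000
  set.seed(6)
  rp <- periodic_rpeaks(220, 250, fs)
  burst <- sin(2 * pi * 6 * seq(0, 0.149, by = 1 / fs)) *
    sin(pi * seq(0, 1, length.out = 38))^2
  s_burst <- pacorrect:::pink_noise(n)
  for (p in rp$indices) {
    s <- p + round(0.25 * fs)
    if (s + 37 <= n) s_burst[s:(s + 37)] <- s_burst[s:(s + 37)] + 5 * burst
  }
  s_alpha <- sin(2 * pi * 10 * (0:(n - 1)) / fs + runif(1, 0, 2 * pi))
  S <- rbind(s_burst, s_alpha, rep(0, n))
  dec <- manual_decomposition(S, diag(3), fs, labels = c("C1", "C2", "C3"))
  sel <- score_wave(dec, rp)
  expect_gt(sel$scores[1], 3)
  expect_true(sel$mask[1])
  expect_equal(sel$scores[2], 1, tolerance = 0.1)
  expect_false(sel$mask[2])
  expect_equal(sel$scores[3], 0)       # all-zero source
  expect_false(sel$mask[3])
})

test_that("selection scores are invariant to sign flips and permutations", {
  fx <- three_source_fixture()
  flip <- function(dec, k) {
    dec$sources[k, ] <- -dec$sources[k, ]
    dec$mixing[, k] <- -dec$mixing[, k]
    dec$unmixing[k, ] <- -dec$unmixing[k, ]
    dec
  }
  perm <- function(dec, p) {
    dec$sources <- dec$sources[p, , drop = FALSE]
    dec$mixing <- dec$mixing[, p, drop = FALSE]
    dec$unmixing <- dec$unmixing[p, , drop = FALSE]
    dec
  }
  part <- partition_channels(pa_montage(6))
  cfg6 <- tiny_config(3, n_channels = 6, duration = 60, alpha_channels = c("C3", "C4"))
  tmpl <- build_pa_templates(generate_background(cfg6), generate_rr(cfg6), part)
  scorers <- list(
    function(d) score_pvaf(d, fx$ref, fx$rpeaks)$scores,
    function(d) score_corr(d, tmpl, fx$rpeaks)$scores,
    function(d) score_pacf(d, fx$rpeaks)$scores,
    function(d) score_wave(d, fx$rpeaks)$scores)
  for (sc in scorers) {
    base <- sc(fx$dec)
    expect_equal(sc(flip(fx$dec, 1)), base, tolerance = 1e-8)
    expect_equal(sc(perm(fx$dec, c(3, 1, 2))), base[c(3, 1, 2)],
                 tolerance = 1e-8)
  }
})

test_that("apply_selection delegates and validates", {
  fx <- three_source_fixture()
  sel <- selection_result("pvaf", c(0, 0, 0), rep(FALSE, 3), "none")
  out <- apply_selection(fx$ref, fx$dec, sel)
  expect_equal(out$data, fx$ref$data, ignore_attr = TRUE)
  expect_equal(out$meta$removal$method, "pvaf")
  bad <- selection_result("pvaf", c(0, 0), c(TRUE, FALSE), "short")
  expect_error(apply_selection(fx$ref, fx$dec, bad), "mask length")
})
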