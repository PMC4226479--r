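#' Standard 64-channel montage for simulations
#'
#' A 10-10 extension of the 10-20 layout: 64 labels that all parse under
#' [partition_channels] (odd = left, even = right, z = midline),
#' including the occipital trio O1/O2/Oz.
#'
#' @param n number of channels (<= 64).
#' @return character vector of labels.
#' @export
pa_montage <- function(n = 64L) {
  labs <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
            "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz", "Oz",
            "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6",
            "TP9", "TP10", "F1", "F2", "C1", "C2", "P1", "P2",
            "AF3", "AF4", "FC3", "FC4", "CP3", "CP4", "PO3", "PO4",
            "F5", "F6", "C5", "C6", "P5", "P6", "AF7", "AF8",
            "FT7", "FT8", "TP7", "TP8", "PO7", "PO8", "F9", "F10",
            "Iz", "AFz", "CPz", "POz")
  if (n > length(labs)) stop("montage supports at most ", length(labs), " channels")
  labs[seq_len(n)]
}

#' Synthetic EEG-in-MR configuration
#'
#' The stated world of the generator. Defaults describe the canonical
#' reference fixture: 64 channels at 250 Hz for 360 s, R-R intervals of
#' 1.0 +/- 0.05 s, pulse artifact at epoch signal-to-background RMS
#' ratio 1.0 with 30% sinusoidal amplitude drift over the recording,
#' continuous ~10 Hz occipito-parietal alpha on a 1/f background.
#'
#' @param n_channels number of channels (default 64).
#' @param fs sampling rate in Hz (default 250).
#' @param duration recording length in s (default 360).
#' @param rr_mean,rr_sd R-R interval mean and sd in s (defaults 1.0,
#'   0.05; `rr_sd < rr_mean / 3` required).
#' @param artifact_gain artifact epoch-RMS relative to the background
#'   RMS (default 1).
#' @param artifact_drift fractional amplitude modulation of the artifact
#'   across the recording (default 0.3).
#' @param latency_jitter_ms per-beat artifact latency jitter, uniform in
#'   +/- this many ms (default 20).
#' @param alpha_freq alpha frequency in Hz (default 10).
#' @param alpha_channels labels carrying the alpha rhythm (default
#'   occipito-parietal).
#' @param alpha_rms alpha RMS amplitude in microvolts (default 5).
#' @param background_rms 1/f background RMS in microvolts (default 10).
#' @param noise_exponent 1/f spectral slope (default 1).
#' @param n_artifact_sources number of distinct artifact generators
#'   (default 5).
#' @param seed integer master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 64L, fs = 250, duration = 360,
                         rr_mean = 1.0, rr_sd = 0.05,
                         artifact_gain = 1.0, artifact_drift = 0.3,
                         latency_jitter_ms = 20,
                         alpha_freq = 10,
                         alpha_channels = c("O1", "O2", "Oz", "P3", "P4", "Pz", "PO3", "PO4"),
                         alpha_rms = 5, background_rms = 10,
                         noise_exponent = 1,
                         n_artifact_sources = 5L, seed = 1L) {
  montage <- pa_montage(n_channels)
  stopifnot(fs > 0, duration > 0, rr_mean > 0, rr_sd >= 0,
            artifact_gain >= 0, artifact_drift >= 0, artifact_drift < 1,
            alpha_freq > 0, alpha_rms >= 0, background_rms > 0)
  if (rr_sd >= rr_mean / 3) stop("rr_sd must be below rr_mean / 3")
  alpha_channels <- intersect(alpha_channels, montage)
  if (!length(alpha_channels)) stop("alpha_channels must intersect the montage")
  structure(list(n_channels = as.integer(n_channels), fs = fs, duration = duration,
                 rr_mean = rr_mean, rr_sd = rr_sd,
                 artifact_gain = artifact_gain, artifact_drift = artifact_drift,
                 latency_jitter_ms = latency_jitter_ms,
                 alpha_freq = alpha_freq, alpha_channels = alpha_channels,
                 alpha_rms = alpha_rms, background_rms = background_rms,
                 noise_exponent = noise_exponent,
                 n_artifact_sources = as.integer(n_artifact_sources),
                 montage = montage, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulated R-R series
#'
#' Draws R-R intervals from a truncated normal (rejection sampling
#' inside +/- 3 sd, floored at 0.3 s) and cumulates them into peak
#' positions, leaving headroom for a 0--700 ms window after the last
#' peak. Deterministic given the config seed.
#'
#' @param config a [synth_config].
#' @return an [rpeak_series].
#' @export
generate_rr <- function(config) {
  with_seed(config$seed + 101L, {
    t_end <- config$duration - 0.8
    if (t_end <= config$rr_mean + 0.5)
      stop("duration too short for 2 peaks")
    draw_rr <- function() {
      repeat {
        v <- stats::rnorm(1, config$rr_mean, config$rr_sd)
        if (abs(v - config$rr_mean) <= 3 * config$rr_sd && v > 0.3) return(v)
      }
    }
    times <- 0.5
    repeat {
      nxt <- times[length(times)] + draw_rr()
      if (nxt > t_end) break
      times <- c(times, nxt)
    }
    rpeak_series(round(times * config$fs) + 1L, config$fs,
                 n_total = round(config$duration * config$fs))
  })
}

# One pulse-artifact kernel over the 0-700 ms window: an early damped
# 3-6 Hz oscillation, a slow mid-latency lobe, and a small alpha-range
# ringlet so the artifact spectrum has its mass in delta-theta with a
# secondary alpha lobe.
pa_kernel <- function(fs, osc_freq = 4.5, osc_t0 = 0.05, osc_tau = 0.15,
                      lobe_t0 = 0.35, lobe_w = 0.12, ring_amp = 0.25) {
  t <- seq(0, 0.7 - 1 / fs, by = 1 / fs)
  osc <- ifelse(t >= osc_t0,
                sin(2 * pi * osc_freq * (t - osc_t0)) * exp(-(t - osc_t0) / osc_tau), 0)
  lobe <- 0.8 * exp(-(t - lobe_t0)^2 / (2 * lobe_w^2))
  ring <- ifelse(t >= 0.10,
                 ring_amp * sin(2 * pi * 10 * (t - 0.10)) * exp(-(t - 0.10) / 0.06), 0)
  k <- osc + lobe + ring
  k * tukey_taper(length(k), 0.1)
}

tukey_taper <- function(n, frac) {
  w <- rep(1, n)
  m <- max(2L, round(frac * n))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  w[1:m] <- ramp
  w[(n - m + 1):n] <- rev(ramp)
  w
}

# Smooth lateralized topography for artifact source j: positive weights
# over the left hemisphere, negative over the right, small on the
# midline. Drawn once per source under the config seed.
pa_topography <- function(config, j) {
  part <- partition_channels(config$montage)
  with_seed(config$seed + 211L + j, {
    w <- numeric(config$n_channels)
    names(w) <- config$montage
    w[part$left] <- stats::runif(length(part$left), 0.4, 1)
    w[part$right] <- -stats::runif(length(part$right), 0.4, 1)
    w[part$mesial] <- stats::runif(length(part$mesial), -0.15, 0.15)
    w
  })
}

#' Simulated pulse artifact
#'
#' Each R peak spawns a 0--700 ms kernel (damped 3--6 Hz oscillation
#' plus a slow lobe and a small alpha-range ringlet), mixed to the scalp
#' through `n_artifact_sources` smooth topographies that are positive
#' over the left hemisphere and negative over the right. Amplitude
#' drifts sinusoidally across the recording with fractional depth
#' `artifact_drift` (monotone half-period: the recording starts at
#' `1 - drift` and ends at `1 + drift` times the nominal gain) and each
#' beat is jittered by up to +/-`latency_jitter_ms`. The output is
#' scaled so the mean artifact RMS inside the pulse-artifact epochs
#' equals `artifact_gain * background_rms`.
#'
#' @param rpeaks an [rpeak_series].
#' @param config a [synth_config].
#' @return list with `recording` (artifact-only [eeg_recording]),
#'   `sources` (n_artifact_sources x samples unit-variance trains) and
#'   `mixing` (channels x n_artifact_sources).
#' @export
generate_artifact <- function(rpeaks, config) {
  fs <- config$fs
  n <- round(config$duration * fs)
  nsrc <- config$n_artifact_sources
  jit_max <- round(config$latency_jitter_ms / 1000 * fs)
  kernels <- lapply(seq_len(nsrc), function(j)
    pa_kernel(fs,
              osc_freq = 3 + 3 * (j - 1) / max(1, nsrc - 1),
              osc_t0 = 0.03 + 0.02 * (j %% 3),
              lobe_t0 = 0.30 + 0.03 * (j %% 4),
              ring_amp = 0.15 + 0.05 * (j %% 3)))
  drift_gain <- function(tt) 1 - config$artifact_drift * cos(pi * tt / config$duration)
  src <- matrix(0, nsrc, n)
  with_seed(config$seed + 307L, {
    for (j in seq_len(nsrc)) {
      jit <- if (jit_max > 0) sample(-jit_max:jit_max, length(rpeaks$indices), TRUE)
             else rep(0L, length(rpeaks$indices))
      amp <- drift_gain(rpeaks$indices / fs) *
        (1 + 0.1 * stats::rnorm(length(rpeaks$indices)))
      k <- kernels[[j]]
      for (b in seq_along(rpeaks$indices)) {
        s <- rpeaks$indices[b] + jit[b]
        e <- s + length(k) - 1L
        if (s < 1L || e > n) next
        src[j, s:e] <- src[j, s:e] + amp[b] * k
      }
    }
  })
  if (config$artifact_gain == 0) {
    rec <- eeg_recording(matrix(0, config$n_channels, n), fs, config$montage)
    return(list(recording = rec, sources = src * 0,
                mixing = matrix(0, config$n_channels, nsrc)))
  }
  mix <- sapply(seq_len(nsrc), function(j) pa_topography(config, j)) / sqrt(nsrc)
  data <- mix %*% src
  # calibrate: mean within-PA-epoch RMS across channels = gain * background RMS
  rng <- cbind(rpeaks$indices, pmin(rpeaks$indices + round(0.7 * fs) - 1L, n))
  idx <- unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]))
  rms <- sqrt(mean(data[, idx]^2))
  scale <- config$artifact_gain * config$background_rms / rms
  list(recording = eeg_recording(data * scale, fs, config$montage),
       sources = src, mixing = mix * scale)
}

#' Simulated resting background EEG
#'
#' Per-channel 1/f^`noise_exponent` Gaussian noise with a shared
#' common-mode 1/f term (spatial correlation), plus an
#' amplitude-modulated alpha oscillation on the configured channels.
#' The alpha phase is random with respect to the cardiac cycle.
#'
#' @inheritParams generate_artifact
#' @return an artifact-free [eeg_recording] (stage `"raw"`).
#' @export
generate_background <- function(config) {
  fs <- config$fs
  n <- round(config$duration * fs)
  if (n < 2) stop("zero-duration configuration")
  with_seed(config$seed + 409L, {
    common <- pink_noise(n, config$noise_exponent)
    data <- matrix(0, config$n_channels, n)
    for (c in seq_len(config$n_channels)) {
      own <- pink_noise(n, config$noise_exponent)
      data[c, ] <- config$background_rms * (sqrt(0.75) * own + 0.5 * common)
    }
    rownames(data) <- config$montage
    if (config$alpha_rms > 0) {
      t <- (seq_len(n) - 1) / fs
      phase <- stats::runif(1, 0, 2 * pi)
      env_raw <- pink_noise(n, 2)           # slow envelope
      env <- 1 + 0.6 * env_raw / max(abs(env_raw)) * 3
      env <- pmax(env, 0.1)
      osc <- env * sin(2 * pi * config$alpha_freq * t + phase)
      osc <- osc / sqrt(mean(osc^2))
      for (ch in config$alpha_channels) {
        gain <- stats::runif(1, 0.7, 1)
        data[ch, ] <- data[ch, ] + config$alpha_rms * gain * osc
      }
    }
    eeg_recording(data, fs, config$montage)
  })
}

#' Simulated ECG channel
#'
#' A QRS-T kernel train at the ground-truth R peaks, plus baseline
#' wander and measurement noise.
#'
#' @inheritParams generate_artifact
#' @return numeric vector, ECG in microvolts.
#' @export
generate_ecg <- function(rpeaks, config) {
  fs <- config$fs
  n <- round(config$duration * fs)
  t <- seq(-0.1, 0.4, by = 1 / fs)
  qrs <- 800 * exp(-t^2 / (2 * 0.008^2)) -
    150 * exp(-(t + 0.028)^2 / (2 * 0.010^2)) -
    220 * exp(-(t - 0.030)^2 / (2 * 0.012^2)) +
    140 * exp(-(t - 0.25)^2 / (2 * 0.045^2))
  center <- which.min(abs(t))
  ecg <- numeric(n)
  for (p in rpeaks$indices) {
    s <- p - center + 1L; e <- s + length(qrs) - 1L
    a <- max(s, 1L); b <- min(e, n)
    ecg[a:b] <- ecg[a:b] + qrs[(a - s + 1L):(b - s + 1L)]
  }
  with_seed(config$seed + 503L, {
    tt <- (seq_len(n) - 1) / fs
    ecg + 80 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi)) +
      20 * stats::rnorm(n)
  })
}

#' @rdname generate_ecg
#' @param fs sampling rate in Hz.
#' @return `qrs_template`: a short R-centered QRS waveform usable as the
#'   matched-filter template of [detect_r_peaks].
#' @export
qrs_template <- function(fs) {
  t <- seq(-0.06, 0.06, by = 1 / fs)
  800 * exp(-t^2 / (2 * 0.008^2)) -
    150 * exp(-(t + 0.028)^2 / (2 * 0.010^2)) -
    220 * exp(-(t - 0.030)^2 / (2 * 0.012^2))
}

#' Generate a full ground-truthed dataset
#'
#' Assembles background, artifact, their sum, and the ECG trace, all
#' deterministic under the config seed. `mixed = clean + artifact`
#' holds sample-wise by construction.
#'
#' @param config a [synth_config].
#' @return object of class `synthetic_dataset`: `mixed`, `clean`,
#'   `artifact` ([eeg_recording]s), `ecg`, `rpeaks`, `artifact_sources`,
#'   `artifact_mixing`, `config`.
#' @export
generate_dataset <- function(config) {
  rpeaks <- generate_rr(config)
  clean <- generate_background(config)
  art <- generate_artifact(rpeaks, config)
  mixed <- eeg_recording(clean$data + art$recording$data, config$fs,
                         config$montage)
  structure(list(mixed = mixed, clean = clean, artifact = art$recording,
                 ecg = generate_ecg(rpeaks, config), rpeaks = rpeaks,
                 artifact_sources = art$sources,
                 artifact_mixing = art$mixing,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d ch x %.0f s @ %g Hz, %d R peaks, gain %.2g, drift %.2g, seed %d\n",
              x$config$n_channels, x$config$duration, x$config$fs,
              length(x$rpeaks$indices), x$config$artifact_gain,
              x$config$artifact_drift, x$config$seed))
  invisible(x)
}

#' Ground-truth decomposition with known artifact and neural sources
#'
#' Builds an `ica_decomposition` directly from a known source model --
#' `n_artifact` R-locked artifact trains and `n_neural` neural sources
#' (alpha-band oscillations and 1/f noise) mixed through random smooth
#' topographies -- bypassing ICA. Used to evaluate the selection
#' criteria against ground truth.
#'
#' @param config a [synth_config].
#' @param n_artifact,n_neural source counts (defaults 5 and 5).
#' @return list with `dec` (an `ica_decomposition`), `truth` (logical,
#'   `TRUE` = artifact source), and `rpeaks`.
#' @export
synthetic_decomposition <- function(config, n_artifact = 5L, n_neural = 5L) {
  rpeaks <- generate_rr(config)
  cfg_art <- config; cfg_art$n_artifact_sources <- as.integer(n_artifact)
  art <- generate_artifact(rpeaks, cfg_art)
  n <- ncol(art$sources)
  fs <- config$fs
  neural <- with_seed(config$seed + 601L, {
    t <- (seq_len(n) - 1) / fs
    rows <- lapply(seq_len(n_neural), function(j) {
      if (j <= 2) {
        env_raw <- pink_noise(n, 2)
        env <- pmax(1 + 1.5 * env_raw / max(abs(env_raw)), 0.1)
        env * sin(2 * pi * (config$alpha_freq + j - 1) * t + stats::runif(1, 0, 2 * pi))
      } else pink_noise(n, config$noise_exponent)
    })
    do.call(rbind, rows)
  })
  src <- rbind(art$sources, neural)
  src <- src / apply(src, 1, stats::sd)
  k <- n_artifact + n_neural
  mix <- with_seed(config$seed + 701L, {
    m <- sapply(seq_len(n_artifact), function(j) pa_topography(config, j))
    m2 <- matrix(stats::rnorm(config$n_channels * n_neural), config$n_channels)
    cbind(m, m2 / sqrt(colSums(m2^2))[col(m2)] * sqrt(config$n_channels) * 0.5)
  })
  unmix <- solve(crossprod(mix), t(mix))   # pseudo-inverse: unmix %*% mix = I
  dec <- structure(list(unmixing = unmix, mixing = mix, sources = src,
                        interval_mode = "whole", rank = k,
                        seed = config$seed, center = rep(0, config$n_channels),
                        labels = config$montage, fs = fs,
                        iterations = 0L, converged = TRUE),
                   class = "ica_decomposition")
  list(dec = dec, truth = rep(c(TRUE, FALSE), c(n_artifact, n_neural)),
       rpeaks = rpeaks)
}
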