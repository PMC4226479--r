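# Shared fixtures, built once per test run.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_channels = 12L, duration = 80, seed = seed,
         alpha_channels = c("O1", "O2", "Oz")),
    list(...))
  do.call(synth_config, args)
}

# cache expensive objects across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_dataset <- function(seed = 1) {
  cached(paste0("ds", seed), generate_dataset(tiny_config(seed)))
}

four_source_fixture <- function(n = 12000, seed = 42) {
  set.seed(seed)
  S <- rbind(ifelse(runif(n) < 0.1, rnorm(n, 0, 3), rnorm(n, 0, 0.3)), # super-G
             sign(rnorm(n)) * abs(rnorm(n))^2,                         # super-G
             runif(n, -1, 1),                                          # sub-G
             rnorm(n))                                                 # Gaussian
  A <- matrix(rnorm(16), 4, 4)
  rec <- eeg_recording(A %*% S, 250, c("C1", "C2", "C3", "C4"),
                       stage = "post_obs")
  list(rec = rec, S = S, A = A)
}

ica4 <- function() {
  cached("ica4", {
    f <- four_source_fixture()
    f$dec <- fit_ica(f$rec, seed = 7)
    f
  })
}

# epoch-averaged RMS of a (residual) recording over the PA window
pa_epoch_avg_rms <- function(rec, rpeaks, window = epoch_window(0, 700)) {
  ep <- extract_epochs(rec, rpeaks, window)
  sqrt(mean(apply(ep$epochs, c(2, 3), mean)^2))
}

# strictly periodic R peaks for constructed-decomposition tests
periodic_rpeaks <- function(n_peaks, period_samples, fs = 250) {
  rpeak_series(seq(1L, by = period_samples, length.out = n_peaks), fs)
}

# minimal hand-built decomposition (bypasses ICA)
manual_decomposition <- function(sources, mixing, fs = 250,
                                 labels = paste0("C", seq_len(nrow(mixing)))) {
  k <- nrow(sources)
  unmix <- solve(crossprod(mixing), t(mixing))
  structure(list(unmixing = unmix, mixing = mixing, sources = sources,
                 interval_mode = "whole", rank = k, seed = 0L,
                 center = rep(0, nrow(mixing)), labels = labels, fs = fs,
                 iterations = 0L, converged = TRUE),
            class = "ica_decomposition")
}
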