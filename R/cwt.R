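#' Complex-Morlet continuous wavelet transform (magnitude)
#'
#' Constant-Q analytic Morlet filter bank. The wavelet at analysis
#' frequency `f` is `exp(2*pi*1i*f*t) * exp(-t^2 / (2*sigma_t^2))` with
#' `sigma_t = q / (2*pi*f)`, i.e. a fixed ratio `q` between the row's
#' center frequency and its spectral bandwidth. The default `q = 2.5`
#' reproduces the printed wavelet settings used for component inspection
#' (center frequency 14.591 Hz with bandwidth 5.836 Hz: a ratio of 2.5).
#'
#' Each row is normalized so a unit-amplitude stationary sinusoid at the
#' row frequency yields magnitude 1 (instantaneous-amplitude, "gabor"
#' normalization); the normalization constant is computed numerically
#' from the kernel's discrete frequency response.
#'
#' @param x numeric vector (a source activation or channel signal).
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies in Hz.
#' @param q center-frequency-to-bandwidth ratio (default 2.5).
#' @return matrix `length(freqs)` x `length(x)` of CWT magnitudes, with
#'   attributes `freqs`, `fs` and `coi_samples` (per-row half-width of
#'   the cone of influence at the signal edges, in samples).
#' @export
cwt_morlet <- function(x, fs, freqs, q = 2.5) {
  x <- as.numeric(x)
  n <- length(x)
  out <- matrix(0, length(freqs), n)
  coi <- integer(length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_t <- q / (2 * pi * f)
    half <- min(ceiling(6 * sigma_t * fs), n - 1L)   # 6 sigma: truncation sidelobes < 1e-7
    t <- (-half:half) / fs
    k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
    # response of the kernel to e^{2 pi i f t}: row gain at its own frequency
    gain <- abs(sum(k * exp(-2i * pi * f * t)))
    k <- 2 * k / gain          # unit sinusoid at f -> |CWT| = 1
    out[i, ] <- Mod(conv_same(x, k))
    coi[i] <- half
  }
  attr(out, "freqs") <- freqs
  attr(out, "fs") <- fs
  attr(out, "coi_samples") <- coi
  out
}

# centered ("same") complex convolution via FFT
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  half <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  K <- stats::fft(c(k, rep(0+0i, nf - m)))
  full <- stats::fft(X * K, inverse = TRUE) / nf
  full[(half + 1L):(half + n)]
}

#' Log-spaced analysis frequency grids
#'
#' `wave_freqs()` is the component-inspection grid: 1 to 20 Hz in 20
#' logarithmically spaced steps (endpoints included). `tfc_freqs()` is
#' the denser grid used for the time-frequency validation maps.
#'
#' @param n number of frequencies.
#' @param lo,hi band edges in Hz.
#' @return numeric vector of frequencies in Hz.
#' @export
wave_freqs <- function(n = 20L, lo = 1, hi = 20) exp(seq(log(lo), log(hi), length.out = n))

#' @rdname wave_freqs
#' @export
tfc_freqs <- function(n = 40L, lo = 1, hi = 20) exp(seq(log(lo), log(hi), length.out = n))

# Average a freq x samples magnitude map over epochs around R peaks.
# The CWT is computed on the continuous signal, so only recording-edge
# regions are unreliable: epochs overlapping the widest cone of
# influence are dropped.
epoch_average_map <- function(mag, rpeaks, window, fs) {
  ns <- window_samples(window, fs)
  off <- window_offset(window, fs)
  n <- ncol(mag)
  coi <- max(attr(mag, "coi_samples"))
  starts <- rpeaks$indices + off
  ok <- starts >= (1L + coi) & (starts + ns - 1L) <= (n - coi)
  starts <- starts[ok]
  if (!length(starts)) stop("no epoch clear of the cone of influence")
  acc <- matrix(0, nrow(mag), ns)
  for (s in starts) acc <- acc + mag[, s:(s + ns - 1L), drop = FALSE]
  map <- acc / length(starts)
  attr(map, "freqs") <- attr(mag, "freqs")
  attr(map, "fs") <- fs
  attr(map, "n_epochs") <- length(starts)
  map
}
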