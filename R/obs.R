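#' Fit an Optimal Basis Set (OBS) pulse-artifact model
#'
#' For each channel, stacks the pulse-artifact epochs, takes their mean as
#' the artifact template, and the first `n_pc` principal components of the
#' mean-removed stack as the basis of beat-to-beat template variation.
#' The default of 3 principal components follows the standard OBS
#' formulation.
#'
#' @param epochs an `epoch_set` over the pulse-artifact window.
#' @param n_pc number of principal components (default 3; `0` keeps only
#'   the mean template).
#' @return An object of class `obs_model`: `mean` (channels x samples),
#'   `basis` (channels x samples x n_pc, orthonormal per channel),
#'   `explained` (channels x n_pc fractional explained variance),
#'   `window`, `fs`, `labels`.
#' @export
fit_obs <- function(epochs, n_pc = 3L) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_pc <- as.integer(n_pc)
  if (n_pc < 0L) stop("n_pc must be >= 0")
  d <- dim(epochs$epochs)          # epochs x channels x samples
  ne <- d[1]; nc <- d[2]; ns <- d[3]
  if (ne < n_pc + 1L) stop("insufficient epochs for basis: need at least n_pc + 1")
  mean_t <- matrix(0, nc, ns)
  basis <- array(0, dim = c(nc, ns, n_pc))
  explained <- matrix(0, nc, n_pc)
  for (c in seq_len(nc)) {
    stack <- epochs$epochs[, c, ]                 # epochs x samples
    if (ne == 1L) stack <- matrix(stack, nrow = 1)
    mu <- colMeans(stack)
    mean_t[c, ] <- mu
    if (n_pc > 0L) {
      centered <- sweep(stack, 2, mu)
      sv <- svd(centered, nu = 0, nv = n_pc)
      tot <- sum(centered^2)
      if (tot > .Machine$double.eps * ne * ns) {
        basis[c, , ] <- sv$v
        explained[c, ] <- sv$d[seq_len(n_pc)]^2 / tot
      } # degenerate stack: zero basis, zero explained variance
    }
  }
  structure(list(mean = mean_t, basis = basis, explained = explained,
                 n_pc = n_pc, window = epochs$window, fs = epochs$fs,
                 labels = epochs$labels),
            class = "obs_model")
}

#' @export
print.obs_model <- function(x, ...) {
  cat(sprintf("<obs_model> %d channels, %d samples/epoch, n_pc=%d, mean explained %.1f%%\n",
              nrow(x$mean), ncol(x$mean), x$n_pc, 100 * mean(rowSums(x$explained))))
  invisible(x)
}

#' Subtract the OBS pulse-artifact template from a recording
#'
#' Within every pulse-artifact window, each channel's observed segment is
#' regressed (ordinary least squares) onto the channel's template mean
#' plus principal-component basis, and the fitted artifact is subtracted.
#' Samples outside all windows are untouched. When consecutive windows
#' overlap (short R-R intervals), the later epoch's fit is subtracted
#' only over its non-overlapped tail, avoiding double subtraction.
#'
#' @param rec an [eeg_recording] (any stage; normally `"raw"`).
#' @param model an `obs_model` fitted at the same sampling rate.
#' @param rpeaks the [rpeak_series] defining the windows.
#' @return The corrected [eeg_recording], stage `"post_obs"`.
#' @export
apply_obs <- function(rec, model, rpeaks) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(model, "obs_model"))
  if (!isTRUE(all.equal(model$fs, rec$fs)))
    stop("model/recording mismatch: sampling rates differ")
  if (!identical(model$labels, rec$labels))
    stop("model/recording mismatch: channel labels differ")
  ns <- ncol(model$mean)
  rng <- epoch_ranges(rec, rpeaks, model$window)
  out <- rec$data
  nc <- n_channels(rec)
  # per-channel design [mean, PCs] and its pseudo-inverse, precomputed
  pinv <- vector("list", nc); design <- vector("list", nc)
  for (c in seq_len(nc)) {
    X <- cbind(model$mean[c, ], matrix(model$basis[c, , ], ns, model$n_pc))
    nz <- colSums(X^2) > .Machine$double.eps * ns
    X <- X[, nz, drop = FALSE]
    design[[c]] <- X
    pinv[c] <- list(if (ncol(X)) solve(crossprod(X) +
                                       diag(1e-12 * max(colSums(X^2)), ncol(X)),
                                       t(X)))
  }
  prev_end <- 0L
  for (e in seq_len(nrow(rng))) {
    s <- rng[e, 1]; en <- rng[e, 2]
    apply_from <- max(s, prev_end + 1L)      # skip region already corrected
    for (c in seq_len(nc)) {
      if (is.null(pinv[[c]])) next
      seg <- rec$data[c, s:en]
      fit <- design[[c]] %*% (pinv[[c]] %*% seg)
      idx <- (apply_from - s + 1L):ns
      out[c, apply_from:en] <- out[c, apply_from:en] - fit[idx]
    }
    prev_end <- max(prev_end, en)
  }
  eeg_recording(out, rec$fs, rec$labels, stage = "post_obs", meta = rec$meta)
}

#' One-call OBS correction
#'
#' Convenience wrapper: extract pulse-artifact epochs, fit the model,
#' subtract it.
#'
#' @inheritParams apply_obs
#' @param window the pulse-artifact window (default 0--700 ms).
#' @param n_pc number of principal components (default 3).
#' @return list with `recording` (corrected, stage `"post_obs"`) and
#'   `model` (the fitted `obs_model`).
#' @export
obs_correct <- function(rec, rpeaks, window = epoch_window(0, 700), n_pc = 3L) {
  ep <- extract_epochs(rec, rpeaks, window)
  model <- fit_obs(ep, n_pc = n_pc)
  list(recording = apply_obs(rec, model, rpeaks), model = model)
}
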