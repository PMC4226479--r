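# Internal helpers.

# Evaluate expr with R's RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# 1/f^exponent Gaussian noise, unit standard deviation.
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1e-6, seq_len(n - 1))          # pseudo-frequency index, DC damped
  f <- pmin(f, n - f)                   # symmetric so the output stays real
  amp <- f^(-exponent / 2)
  amp[1] <- 0
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
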