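# Independent oracles used across the test suite.  These deliberately avoid
# the package's own code paths.

# Streak slope (px/line) by least squares on per-line dip centroids of a
# noiseless kymograph rendered with a single streak.
ls_slope_oracle <- function(img) {
  n_lines <- nrow(img)
  n_px <- ncol(img)
  centers <- numeric(n_lines)
  for (i in seq_len(n_lines)) {
    line <- max(img[i, ]) - img[i, ]  # dip -> peak
    j <- which.max(line)
    # unwrap a window around the minimum, circularly
    off <- -3:3
    idx <- ((j - 1 + off) %% n_px) + 1
    w <- line[idx]
    centers[i] <- j + sum(off * w) / sum(w)
  }
  d <- diff(centers)
  d <- (d + n_px / 2) %% n_px - n_px / 2  # unwrap
  mean(d)
}

# Exact uniform-multinomial p for k = 2 via the binomial distribution.
exact_p2_oracle <- function(o, n) {
  stats <- sapply(0:n, function(x) (x - n / 2)^2 / (n / 2) * 2)
  sum(dbinom(0:n, n, 0.5)[stats >= stats[o + 1] - 1e-12])
}

# Exact uniform-multinomial p for k = 3 via a double loop.
exact_p3_oracle <- function(counts) {
  n <- sum(counts)
  e <- n / 3
  obs <- sum((counts - e)^2 / e)
  p <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    cc <- n - a - b
    stat <- ((a - e)^2 + (b - e)^2 + (cc - e)^2) / e
    if (stat >= obs - 1e-12) {
      p <- p + exp(lfactorial(n) - lfactorial(a) - lfactorial(b) -
                     lfactorial(cc) - n * log(3))
    }
  }
  p
}

# Hand Pearson r.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Energy of a signal inside / outside a time window by direct integration.
window_energy <- function(t, x, window) {
  inside <- t >= window[1] & t <= window[2]
  c(inside = sum(x[inside]^2), outside = sum(x[!inside]^2))
}

# Simple FFT bandpass (rectangular) used as an independent check for the
# synthetic PIP energy example.
fft_bandpass_oracle <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

# Out-of-band power fraction of a waveform, excluding the DC bin.
oob_fraction_oracle <- function(x, fs, f_lo, f_hi, guard = 0.5) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  inb <- f >= f_lo - guard & f <= f_hi + guard
  sum(p[!inb]) / sum(p)
}

expect_no_short_window_warning <- function(expr) {
  withCallingHandlers(expr, nv_short_window = function(w)
    invokeRestart("muffleWarning"))
}
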