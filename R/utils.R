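# Internal numerical helpers shared across modules.

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
# Centered moving average with shrinking windows at the edges. k is forced odd.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (k == 1L || n < 2L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered running median; robust against isolated outlier samples.
moving_median <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) k <- if (n %% 2L == 1L) n else n - 1L
  if (k < 3L || n < 3L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Contiguous TRUE runs -> data.frame(start, end) of inclusive indices.
true_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

trapz_integral <- function(t, y) {
  if (length(t) < 2L) return(0)
  pracma::trapz(t, y)
}

# Zero-phase filtering by frequency sampling: the trace is mirror-padded,
# transformed, multiplied by a real symmetric frequency response and
# inverse-transformed.  Stable at any sampling rate, including very low
# normalized cutoffs where recursive filters are numerically fragile.
fft_apply_response <- function(x, fs, response) {
  n <- length(x)
  if (n < 4L) return(x)
  mu <- mean(x)
  y <- x - mu
  npad <- min(n - 1L, as.integer(round(2 * fs)))
  left <- rev(y[seq(2L, npad + 1L)])
  right <- rev(y[seq(n - npad, n - 1L)])
  z <- c(left, y, right)
  m <- length(z)
  nfft <- stats::nextn(m, c(2, 3, 5))
  z <- c(z, numeric(nfft - m))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  f <- pmin(f, fs - f)
  H <- response(f)
  out <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / nfft
  out <- out[npad + seq_len(n)]
  # restore the mean only if the response passes DC
  out + mu * response(0)
}

# Raised-cosine high-pass edge: 0 below f0 - width, 1 above f0 + width.
response_highpass <- function(f0, width = 0.3 * f0) {
  force(f0); force(width)
  function(f) {
    h <- numeric(length(f))
    h[f >= f0 + width] <- 1
    ramp <- f > f0 - width & f < f0 + width
    h[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - (f0 - width)) / (2 * width)))
    h
  }
}

# Notch: zero inside f0 +/- stop_halfwidth with raised-cosine shoulders.
response_notch <- function(f0, stop_halfwidth = 1, ramp = 2) {
  force(f0); force(stop_halfwidth); force(ramp)
  function(f) {
    d <- abs(f - f0)
    h <- rep(1, length(f))
    h[d <= stop_halfwidth] <- 0
    sh <- d > stop_halfwidth & d < stop_halfwidth + ramp
    h[sh] <- 0.5 * (1 - cos(pi * (d[sh] - stop_halfwidth) / ramp))
    h
  }
}

# Low-pass used before decimation.
response_lowpass <- function(f0, width = 0.2 * f0) {
  force(f0); force(width)
  function(f) {
    h <- numeric(length(f))
    h[f <= f0 - width] <- 1
    ramp <- f > f0 - width & f < f0 + width
    h[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - (f0 - width)) / (2 * width)))
    h
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
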