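#' Estimate RBC velocity from a kymograph by line-scanning PIV
#'
#' Cross-correlates sequential line scans in overlapping blocks.  Each line
#' is mean-subtracted and normalized; the cross-spectra of all consecutive
#' line pairs within a block are averaged and inverted to a single
#' normalized circular cross-correlation, whose peak location gives the
#' displacement per line.  The peak is localized to sub-pixel precision by
#' Fourier upsampling of the correlation followed by a 3-point parabolic
#' fit on the fine grid.  Velocity is
#' `shift_px * pixel_size / line_period` (um/ms, i.e. mm/s); positive
#' velocity is motion toward increasing column index.
#'
#' A block whose lines are all constant (no texture) yields a sample with
#' `quality = 0` and `v_mm_s = NA`.  When two correlation values tie at the
#' peak, the smaller absolute shift wins (minimal-motion prior).
#'
#' @param kymo A [kymograph()].
#' @param window_lines Lines per correlation block (>= 4).
#' @param overlap_fraction Fractional overlap of consecutive blocks in
#'   `[0, 1)`.
#' @param max_shift Largest admissible displacement in pixels per line;
#'   defaults to a quarter of the line width and must stay below half of it.
#' @param upsample Fourier upsampling factor for sub-pixel peak search.
#' @return A [velocity_trace()] with one sample per block (block-center
#'   times, signed velocity, normalized correlation peak as quality).
#' @export
#' @examples
#' sim <- generate_kymograph(2, n_lines = 512, n_pixels = 64,
#'                           line_period = 1, seed = 2)
#' tr <- estimate_velocity(sim$kymograph)
#' median(tr$v_mm_s)
estimate_velocity <- function(kymo, window_lines = 32, overlap_fraction = 0.5,
                              max_shift = NULL, upsample = 16L) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  n_lines <- nrow(img)
  n_px <- ncol(img)
  window_lines <- as.integer(window_lines)
  if (window_lines < 4L) stop("window_lines must be >= 4", call. = FALSE)
  if (window_lines > n_lines) {
    stop("window (", window_lines, " lines) larger than the image (",
         n_lines, " lines)", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  }
  max_shift <- max_shift %||% floor(n_px / 4)
  if (max_shift <= 0 || max_shift >= n_px / 2) {
    stop("max_shift must lie in (0, n_pixels/2)", call. = FALSE)
  }
  upsample <- max(1L, as.integer(upsample))

  step <- max(1L, as.integer(round(window_lines * (1 - overlap_fraction))))
  starts <- seq(1L, n_lines - window_lines + 1L, by = step)

  # mean-subtract every line once; norms decide degenerate (flat) lines
  a <- img - rowMeans(img)
  norms <- sqrt(rowSums(a * a))

  nf <- n_px * upsample
  # fine-grid lags in pixels, index 1 == lag 0, wrapped negative lags
  lag_px <- (seq_len(nf) - 1L) / upsample
  lag_px[lag_px > n_px / 2] <- lag_px[lag_px > n_px / 2] - n_px
  admissible <- abs(lag_px) <= max_shift

  t_s <- v <- q <- numeric(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w] + seq_len(window_lines) - 1L
    t_s[w] <- (starts[w] - 1L + window_lines / 2) * kymo$line_period / 1000
    ok <- norms[idx] > 0
    pair_ok <- ok[-window_lines] & ok[-1L]
    if (!any(pair_ok)) {
      v[w] <- NA_real_; q[w] <- 0
      next
    }
    block <- t(a[idx, , drop = FALSE] / pmax(norms[idx], .Machine$double.eps))
    f <- stats::mvfft(block)
    cs <- Conj(f[, -window_lines, drop = FALSE]) * f[, -1L, drop = FALSE]
    avg <- rowMeans(cs[, pair_ok, drop = FALSE])
    fine <- upsampled_correlation(avg, upsample)
    cand <- which(admissible)
    peak <- cand[order(-fine[cand], abs(lag_px[cand]))[1L]]
    q[w] <- max(0, min(1, fine[peak]))
    v[w] <- refine_peak(fine, peak, nf, lag_px, upsample) *
      kymo$pixel_size / kymo$line_period
  }

  velocity_trace(t_s, v, q)
}

# Inverse FFT of a cross-spectrum zero-padded by `upsample`, giving the
# circular cross-correlation on a grid of 1/upsample pixel.
upsampled_correlation <- function(spec, upsample) {
  n <- length(spec)
  if (upsample == 1L) return(Re(stats::fft(spec, inverse = TRUE)) / n)
  nf <- n * upsample
  padded <- complex(nf)
  half <- n %/% 2L
  padded[seq_len(half + 1L)] <- spec[seq_len(half + 1L)]
  padded[nf - seq_len(n - half - 1L) + 1L] <- spec[n - seq_len(n - half - 1L) + 1L]
  if (n %% 2L == 0L) {
    # split the Nyquist bin symmetrically
    padded[half + 1L] <- spec[half + 1L] / 2
    padded[nf - half + 1L] <- spec[half + 1L] / 2
  }
  Re(stats::fft(padded, inverse = TRUE)) / n
}

# 3-point parabolic refinement around `peak` on the fine grid; returns the
# sub-pixel shift in pixels.
refine_peak <- function(fine, peak, nf, lag_px, upsample) {
  m1 <- fine[((peak - 2L) %% nf) + 1L]
  p1 <- fine[(peak %% nf) + 1L]
  c0 <- fine[peak]
  denom <- m1 - 2 * c0 + p1
  delta <- if (is.finite(denom) && denom < 0) 0.5 * (m1 - p1) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  lag_px[peak] + delta / upsample
}
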