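#' Generate a synthetic line-scan kymograph with known velocity
#'
#' Renders dark RBC streaks on a bright plasma background (unlabeled cells
#' exclude the intravascular dye, so cells appear as intensity dips).  A set
#' of particles is advected along the position axis by the prescribed
#' velocity profile; positions wrap around the line so streak density is
#' stationary.  The local streak slope on line `i` is exactly
#' `v(t_i) * line_period / pixel_size` pixels/line, and the per-line
#' ground-truth velocity is returned alongside the image.
#'
#' @param velocity_profile Either a single velocity in mm/s or a function
#'   `time_s -> mm/s` evaluated at each line center.
#' @param n_lines,n_pixels Image size (lines x pixels).
#' @param line_period Line period in ms.
#' @param pixel_size Pixel size in micrometers.
#' @param streak_density Expected number of streaks crossing each line.
#' @param contrast Dip depth relative to the background, in `(0, 1]`.
#' @param noise_sd Additive Gaussian noise SD in image units (background is
#'   at 0.85; full scale is `[0, 1]`).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param streak_sigma Gaussian half-width of a streak cross-section in
#'   pixels (point-spread plus cell size).
#' @return A list with elements `kymograph` (a [kymograph()]) and `truth`
#'   (data frame `line`, `time_s`, `v_mm_s`).
#' @export
#' @examples
#' sim <- generate_kymograph(2, n_lines = 256, n_pixels = 64, seed = 1)
#' dim(sim$kymograph)
generate_kymograph <- function(velocity_profile, n_lines, n_pixels,
                               line_period = 1.2, pixel_size = 1,
                               streak_density = 8, contrast = 0.6,
                               noise_sd = 0, seed = 1, streak_sigma = 1.3) {
  n_lines <- as.integer(n_lines)
  n_pixels <- as.integer(n_pixels)
  stopifnot(n_lines >= 2L, n_pixels >= 16L, line_period > 0, pixel_size > 0,
            contrast > 0, contrast <= 1, noise_sd >= 0, streak_sigma > 0)

  t_s <- (seq_len(n_lines) - 0.5) * line_period / 1000
  v <- if (is.function(velocity_profile)) velocity_profile(t_s) else
    rep(as.numeric(velocity_profile), n_lines)
  if (length(v) != n_lines || any(!is.finite(v))) {
    stop("velocity_profile must give a finite velocity for every line",
         call. = FALSE)
  }

  # displacement per line in pixels: mm/s * ms / um == px
  d_px <- v * line_period / pixel_size
  if (max(abs(d_px)) >= n_pixels / 2) {
    stop(sprintf(
      paste0("aliasing: per-line displacement %.2f px exceeds half the line ",
             "width (%d px); reduce velocity or line_period"),
      max(abs(d_px)), n_pixels %/% 2L), call. = FALSE)
  }

  n_streaks <- max(1L, as.integer(round(streak_density)))
  img <- matrix(0, n_lines, n_pixels)
  # cumulative displacement: position on line i = p0 + sum of d over lines < i
  disp <- c(0, cumsum(d_px[-n_lines]))
  half <- as.integer(ceiling(3 * streak_sigma)) + 1L
  rows <- seq_len(n_lines)

  with_seed(seed, {
    p0 <- stats::runif(n_streaks, 0, n_pixels)
    for (j in seq_len(n_streaks)) {
      pos <- (p0[j] + disp) %% n_pixels
      base_col <- floor(pos)
      for (off in -half:half) {
        col <- base_col + off
        val <- exp(-((col - pos)^2) / (2 * streak_sigma^2))
        idx <- cbind(rows, (col %% n_pixels) + 1L)
        img[idx] <- img[idx] + val
      }
    }
    intensity <- 0.85 * (1 - contrast * pmin(img, 1.5) / 1.5)
    if (noise_sd > 0) {
      intensity <- intensity + stats::rnorm(n_lines * n_pixels, 0, noise_sd)
    }
  })
  intensity <- pmin(pmax(intensity, 0), 1)

  list(
    kymograph = kymograph(intensity, line_period = line_period,
                          pixel_size = pixel_size),
    truth = data.frame(line = seq_len(n_lines), time_s = t_s, v_mm_s = v)
  )
}
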