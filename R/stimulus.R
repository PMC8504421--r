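#' Synthesize a band-limited optogenetic drive waveform
#'
#' Sums equal-amplitude sinusoids at every integer frequency from `f_low`
#' to `f_high` inclusive (1 Hz increments), with seeded random phases to
#' bound the crest factor.  The sum is normalized to `[0, 1]` and uniformly
#' quantized to `2^bits` mid-riser levels, emulating export to a 12-bit DAC
#' at 500 Hz.  Shared band-edge integers (e.g. 10 Hz) belong to both
#' adjacent bands' component sets.
#'
#' @param band One-row band definition ([band_definition()] /
#'   [get_band()]).
#' @param duration Waveform length in seconds.
#' @param fs Sampling rate in Hz (default 500).
#' @param bits Quantization depth (default 12).
#' @param seed Integer seed for the component phases.
#' @return Object of class `stimulus_waveform`: `samples` in `[0, 1]`,
#'   `fs`, `band`, `bits`, `component_frequencies`, `phases`.
#' @export
#' @examples
#' w <- synthesize_band_waveform(get_band(default_bands(), "theta"))
#' w$component_frequencies
synthesize_band_waveform <- function(band, duration = 60, fs = 500,
                                     bits = 12, seed = 1) {
  stopifnot(nrow(band) == 1L, duration > 0, fs > 0, bits >= 1)
  freqs <- seq(ceiling(band$f_low), floor(band$f_high))
  if (length(freqs) == 0L) stop("band contains no integer frequency", call. = FALSE)
  bad <- freqs[freqs >= fs / 2]
  if (length(bad)) {
    stop("aliasing: component frequencies ", paste(bad, collapse = ", "),
         " Hz are at or above Nyquist (fs/2 = ", fs / 2, " Hz)",
         call. = FALSE)
  }
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  phases <- with_seed(seed, stats::runif(length(freqs), 0, 2 * pi))
  x <- numeric(n)
  for (j in seq_along(freqs)) {
    x <- x + sin(2 * pi * freqs[j] * t + phases[j])
  }
  x <- (x - min(x)) / (max(x) - min(x))
  levels <- 2^bits
  q <- (floor(pmin(x, 1 - .Machine$double.eps) * levels) + 0.5) / levels

  structure(list(samples = q, fs = fs, band = band$name, bits = as.integer(bits),
                 component_frequencies = freqs, phases = phases,
                 duration = duration),
            class = "stimulus_waveform")
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf(
    "<stimulus_waveform> %s | %d components (%g-%g Hz) | %g s @ %g Hz | %d-bit\n",
    x$band, length(x$component_frequencies), min(x$component_frequencies),
    max(x$component_frequencies), x$duration, x$fs, x$bits))
  invisible(x)
}

#' Write a stimulus waveform as CSV
#'
#' Columns: `time_s`, `level_0_1`, and the integer DAC code `level_int`
#' (`0 .. 2^bits - 1`).
#'
#' @param waveform A [synthesize_band_waveform()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "stimulus_waveform"))
  n <- length(waveform$samples)
  utils::write.csv(data.frame(
    time_s = (seq_len(n) - 1L) / waveform$fs,
    level_0_1 = waveform$samples,
    level_int = as.integer(round(waveform$samples * 2^waveform$bits - 0.5))
  ), path, row.names = FALSE)
  invisible(path)
}

#' Build a randomized stimulation schedule
#'
#' Per block, the bands are presented once each in seeded random order, for
#' `stim_duration` seconds with `isi` seconds between stimuli.
#'
#' @param bands Band definition data frame.
#' @param stim_duration Stimulus length in seconds (default 60).
#' @param isi Interstimulus interval in seconds (default 60).
#' @param n_blocks Number of blocks (>= 1).
#' @param seed Integer seed for the permutations.
#' @return Data frame of class `stimulation_schedule`: `block`, `band`,
#'   `start_s`, `duration_s`; attributes `isi`, `seed`.
#' @export
build_schedule <- function(bands = default_bands(), stim_duration = 60,
                           isi = 60, n_blocks = 1, seed = 1) {
  if (is.null(bands) || nrow(bands) == 0L) {
    stop("band list must not be empty", call. = FALSE)
  }
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1L, stim_duration > 0, isi >= 0)
  nb <- nrow(bands)
  orders <- with_seed(seed, {
    lapply(seq_len(n_blocks), function(b) sample.int(nb))
  })
  slot <- stim_duration + isi
  entries <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(block = b,
               band = bands$name[orders[[b]]],
               start_s = (b - 1L) * nb * slot + (seq_len(nb) - 1L) * slot,
               duration_s = stim_duration,
               stringsAsFactors = FALSE)
  }))
  class(entries) <- c("stimulation_schedule", "data.frame")
  attr(entries, "isi") <- isi
  attr(entries, "seed") <- as.integer(seed)
  entries
}
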