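#' DC-coupled LFP trace container
#'
#' Holds a local field potential recording in mV at a fixed sampling rate.
#' The DC component is preserved on ingest: spreading-depolarization
#' detection reads the raw, unfiltered trace, while power analyses use a
#' filtered copy produced by [preprocess_for_power()].
#'
#' @param samples Numeric vector of potentials in mV.
#' @param fs Sampling rate in Hz (default 10000).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs = 10000, t0 = 0) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, t0 = as.numeric(t0)),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz | %.1f s | mean %.3f mV\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              mean(x$samples)))
  invisible(x)
}

#' @export
length.lfp_trace <- function(x) length(x$samples)

#' Time axis of an LFP trace
#' @param trace An [lfp_trace()].
#' @return Sample times in seconds.
#' @export
lfp_time <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$fs
}

#' Write / read an LFP trace as a two-column CSV
#'
#' Columns are `time_s` and `potential_mV`.
#'
#' @param trace An [lfp_trace()].
#' @param path CSV path.
#' @return `path` (write) or an [lfp_trace()] (read).
#' @export
write_lfp <- function(trace, path) {
  stopifnot(inherits(trace, "lfp_trace"))
  utils::write.csv(
    data.frame(time_s = lfp_time(trace), potential_mV = trace$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "potential_mV") %in% names(d))) {
    stop("expected columns time_s, potential_mV in ", path, call. = FALSE)
  }
  dt <- diff(d$time_s)
  if (length(dt) < 1L || any(dt <= 0)) stop("time_s must be increasing", call. = FALSE)
  lfp_trace(d$potential_mV, fs = 1 / stats::median(dt), t0 = d$time_s[1L])
}

# Index range of a [start, end] second window within the trace; errors if the
# window falls outside the recording.
window_indices <- function(trace, window, what = "window") {
  t <- lfp_time(trace)
  eps <- 0.5 / trace$fs
  if (window[1L] >= window[2L]) stop(what, " must satisfy start < end", call. = FALSE)
  if (window[1L] < t[1L] - eps || window[2L] > t[length(t)] + eps) {
    stop(what, " [", window[1L], ", ", window[2L],
         "] s lies outside the trace", call. = FALSE)
  }
  which(t >= window[1L] - eps & t <= window[2L] + eps)
}
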