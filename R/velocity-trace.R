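#' Red-blood-cell velocity trace
#'
#' A time series of signed vessel-axis RBC velocity in mm/s with a per-window
#' quality score (normalized correlation peak height in `[0, 1]`).  Positive
#' velocity means motion toward increasing kymograph column index; arteriole
#' versus venule identity is caller-supplied metadata, not computed here.
#'
#' @param time_s Window-center times in seconds, strictly increasing.
#' @param v_mm_s Signed velocity in mm/s (`NA` where invalid).
#' @param quality Quality score in `[0, 1]` for every sample.
#' @param vessel_class One of `"proximal"`, `"distal"`, `"vein"`,
#'   `"unclassified"` (proximal: within ~100 um of the injection site;
#'   distal: farther than ~1 mm).
#' @return A data frame of class `velocity_trace` with columns
#'   `time_s`, `v_mm_s`, `quality`.
#' @export
velocity_trace <- function(time_s, v_mm_s, quality = rep(1, length(time_s)),
                           vessel_class = "unclassified") {
  time_s <- as.numeric(time_s)
  v_mm_s <- as.numeric(v_mm_s)
  quality <- as.numeric(quality)
  n <- length(time_s)
  if (length(v_mm_s) != n || length(quality) != n) {
    stop("time_s, v_mm_s and quality must have equal length", call. = FALSE)
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(quality)) || any(quality < 0 | quality > 1)) {
    stop("quality must lie in [0, 1] for every sample", call. = FALSE)
  }
  vessel_class <- match.arg(vessel_class,
                            c("unclassified", "proximal", "distal", "vein"))
  out <- data.frame(time_s = time_s, v_mm_s = v_mm_s, quality = quality)
  class(out) <- c("velocity_trace", "data.frame")
  attr(out, "vessel_class") <- vessel_class
  attr(out, "sign_convention") <-
    "positive velocity = motion toward increasing column index"
  out
}

#' Remove low-quality velocity samples
#'
#' Samples whose correlation quality falls below `min_quality` are dropped;
#' the time axis keeps its gaps so that downstream integration can account
#' for missing coverage.
#'
#' @param trace A [velocity_trace()].
#' @param min_quality Threshold in `[0, 1]`; samples with
#'   `quality >= min_quality` are kept.
#' @return The filtered [velocity_trace()]. Warns if nothing survives.
#' @export
quality_filter <- function(trace, min_quality) {
  stopifnot(inherits(trace, "velocity_trace"))
  min_quality <- as.numeric(min_quality)
  if (!is.finite(min_quality) || min_quality < 0) {
    stop("min_quality must be >= 0", call. = FALSE)
  }
  keep <- trace$quality >= min_quality
  out <- trace[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("quality_filter removed every sample (min_quality = ",
            min_quality, ")", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- class(trace)
  attr(out, "vessel_class") <- attr(trace, "vessel_class")
  attr(out, "sign_convention") <- attr(trace, "sign_convention")
  out
}

#' Write / read a velocity trace as CSV
#'
#' Columns are `time_s`, `v_mm_s`, `quality`.
#'
#' @param trace A [velocity_trace()].
#' @param path CSV path.
#' @return `path` (write) or a [velocity_trace()] (read).
#' @export
write_velocity_trace <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_trace
#' @export
read_velocity_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "v_mm_s") %in% names(d))) {
    stop("expected columns time_s, v_mm_s in ", path, call. = FALSE)
  }
  q <- if ("quality" %in% names(d)) d$quality else rep(1, nrow(d))
  velocity_trace(d$time_s, d$v_mm_s, q)
}
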