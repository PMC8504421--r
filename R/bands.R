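#' LFP frequency band definitions
#'
#' The analysis partitions the 2--120 Hz range into the five bands used for
#' band power, wavelet series and stimulation synthesis: theta 2--10 Hz,
#' alpha 10--15 Hz, beta 15--30 Hz, low gamma 30--80 Hz and high gamma
#' 80--120 Hz.  A frequency lying exactly on a shared boundary (e.g. 10 Hz)
#' is assigned to the lower band.
#'
#' @return A data frame with columns `name`, `f_low` and `f_high` (Hz).
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "low_gamma", "high_gamma"),
    f_low = c(2, 10, 15, 30, 80),
    f_high = c(10, 15, 30, 80, 120),
    stringsAsFactors = FALSE
  )
}

#' Construct a single band definition
#'
#' @param name Band label.
#' @param f_low,f_high Band edges in Hz, `f_low < f_high`.
#' @return One-row data frame compatible with [default_bands()].
#' @export
band_definition <- function(name, f_low, f_high) {
  stopifnot(is.character(name), length(name) == 1L)
  f_low <- as.numeric(f_low); f_high <- as.numeric(f_high)
  if (!is.finite(f_low) || !is.finite(f_high) || f_low <= 0 || f_low >= f_high) {
    stop("band requires 0 < f_low < f_high", call. = FALSE)
  }
  data.frame(name = name, f_low = f_low, f_high = f_high,
             stringsAsFactors = FALSE)
}

#' Read band definitions from a YAML file
#'
#' The file maps band names to two-element `[f_low, f_high]` ranges, e.g.
#' `theta: [2, 10]`.
#'
#' @param path YAML file path.
#' @return Band data frame as from [default_bands()].
#' @export
bands_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop("no bands defined in ", path, call. = FALSE)
  out <- do.call(rbind, lapply(names(raw), function(nm) {
    rng <- as.numeric(raw[[nm]])
    if (length(rng) != 2L) {
      stop("band '", nm, "' must be a [f_low, f_high] pair", call. = FALSE)
    }
    band_definition(nm, rng[1L], rng[2L])
  }))
  rownames(out) <- NULL
  out
}

#' Select one band definition by name
#'
#' @param bands Band data frame (e.g. [default_bands()]).
#' @param name Band name.
#' @return The matching one-row band definition.
#' @export
get_band <- function(bands, name) {
  row <- bands[bands$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown band '", name, "'", call. = FALSE)
  row
}
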