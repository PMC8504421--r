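#' Kymograph container
#'
#' A kymograph is a space--time image assembled from repeated line scans along
#' a vessel axis: rows are successive lines (time), columns are positions
#' along the vessel.  Moving red blood cells appear as slanted streaks whose
#' slope (pixels per line) encodes their velocity.
#'
#' @param intensity Numeric matrix, lines x pixels, arbitrary units.
#' @param line_period Line period in ms (0.1--10 ms accepted).
#' @param pixel_size Pixel size along the vessel in micrometers.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensity, line_period, pixel_size) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("intensity must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensity) < 2L) stop("kymograph needs at least 2 lines", call. = FALSE)
  if (ncol(intensity) < 16L) stop("kymograph needs at least 16 pixels per line", call. = FALSE)
  line_period <- as.numeric(line_period)
  pixel_size <- as.numeric(pixel_size)
  if (!is.finite(line_period) || line_period < 0.1 || line_period > 10) {
    stop("line_period must lie in [0.1, 10] ms", call. = FALSE)
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive", call. = FALSE)
  }
  structure(
    list(intensity = intensity, line_period = line_period,
         pixel_size = pixel_size),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d lines x %d px | %.3f ms/line | %.2f um/px | span %.2f s\n",
    nrow(x$intensity), ncol(x$intensity), x$line_period, x$pixel_size,
    nrow(x$intensity) * x$line_period / 1000))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$intensity)

#' Mirror a kymograph along the position axis
#'
#' Reverses the column order, which negates all streak slopes and therefore
#' all encoded velocities.
#'
#' @param kymo A [kymograph()].
#' @return The mirrored kymograph.
#' @export
mirror_kymograph <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  kymo$intensity <- kymo$intensity[, rev(seq_len(ncol(kymo$intensity))), drop = FALSE]
  kymo
}

#' Write a kymograph as TIFF plus JSON sidecar
#'
#' The image is stored as a single-plane 32-bit grayscale TIFF (values
#' clipped to `[0, 1]`); acquisition metadata (`line_period_ms`,
#' `pixel_size_um`, and optionally the generator `seed`) goes to a JSON
#' sidecar with the same stem.
#'
#' @param kymo A [kymograph()].
#' @param path Output TIFF path.
#' @param seed Optional generator seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, seed = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- pmin(pmax(kymo$intensity, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  meta <- list(line_period_ms = kymo$line_period,
               pixel_size_um = kymo$pixel_size)
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path) {
  img <- tiff::readTIFF(path)
  if (is.list(img)) img <- img[[1L]]
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing JSON sidecar for ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  kymograph(img, line_period = meta$line_period_ms,
            pixel_size = meta$pixel_size_um)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

# Time (s) at the center of each line.
kymo_line_times <- function(kymo) {
  (seq_len(nrow(kymo$intensity)) - 0.5) * kymo$line_period / 1000
}
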