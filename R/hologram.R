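#' In-line hologram (recorded intensity image)
#'
#' A single-channel non-negative intensity image in sensor counts, together
#' with the acquisition metadata needed to reconstruct it: pixel pitch and
#' illumination wavelength. Phase information is lost at acquisition; it is
#' recovered downstream by [phase_retrieval()].
#'
#' @param intensity Non-negative numeric matrix (sensor counts).
#' @param pitch Pixel pitch in micrometres (default 1.67, the sensor used
#'   for CSF acquisitions).
#' @param wavelength Illumination wavelength in nanometres.
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, pitch = 1.67, wavelength, channel = c("blue", "green", "red")) {
  channel <- match.arg(channel)
  if (!is.matrix(intensity) || !is.numeric(intensity) || length(intensity) == 0) {
    rlang::abort("`intensity` must be a non-empty numeric matrix.", class = "holocyte_invalid_parameter")
  }
  if (any(intensity < 0)) {
    rlang::abort("hologram intensity must be non-negative.", class = "holocyte_invalid_parameter")
  }
  check_positive_scalar(pitch, "pitch")
  check_positive_scalar(wavelength, "wavelength")
  structure(
    list(intensity = intensity, pitch = pitch, wavelength = wavelength, channel = channel),
    class = "hologram"
  )
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf(
    "<hologram> %s channel, %d x %d px, pitch %.3g um, lambda %.4g nm, mean %.4g counts\n",
    x$channel, nrow(x$intensity), ncol(x$intensity), x$pitch, x$wavelength,
    mean(x$intensity)
  ))
  invisible(x)
}

#' @rdname hologram
#' @param x Object to test.
#' @export
is_hologram <- function(x) inherits(x, "hologram")

#' Write / read a hologram as 16-bit TIFF with a JSON sidecar
#'
#' The intensity image is stored as 16-bit grayscale TIFF; pitch, wavelength
#' and channel go into a JSON sidecar `<path>.json` so a hologram round-trips
#' losslessly (counts are clipped to the 16-bit sensor range on write, as on
#' a real sensor).
#'
#' @param h A [hologram()].
#' @param path Output TIFF path.
#' @return `write_hologram()` returns `path` invisibly; `read_hologram()`
#'   returns a [hologram()].
#' @export
write_hologram <- function(h, path) {
  stopifnot(is_hologram(h))
  counts <- pmin(pmax(round(h$intensity), 0), 65535)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  meta <- list(
    pitch_um = h$pitch, wavelength_nm = h$wavelength, channel = h$channel,
    format = "16-bit grayscale TIFF, counts = pixel * 65535"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hologram(round(img * 65535),
    pitch = meta$pitch_um, wavelength = meta$wavelength_nm,
    channel = meta$channel
  )
}
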