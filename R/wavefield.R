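#' Complex wave field on a regular grid
#'
#' A `wave_field` holds the complex amplitude of a scalar optical field
#' sampled on a rectangular grid at a stated distance from the sensor plane.
#' It is the common currency of the simulation, reconstruction and
#' Z-profiling steps.
#'
#' @param amplitude Complex (or numeric, promoted to complex) matrix of field
#'   values. Dimensionless transmittance/field units.
#' @param pitch Pixel pitch in micrometres. Must be positive.
#' @param wavelength Illumination wavelength in nanometres. Must be positive.
#' @param z_ref Signed distance of this plane from the sensor plane in
#'   micrometres (0 = sensor plane, positive towards the object/source).
#'
#' @return An object of class `wave_field`.
#' @export
#' @examples
#' f <- wave_field(matrix(1 + 0i, 32, 32), pitch = 1.67, wavelength = 457.5)
#' f
wave_field <- function(amplitude, pitch, wavelength, z_ref = 0) {
  if (!is.matrix(amplitude) || nrow(amplitude) < 1 || ncol(amplitude) < 1) {
    rlang::abort("`amplitude` must be a non-empty matrix.", class = "holocyte_invalid_parameter")
  }
  if (!is.complex(amplitude)) {
    if (!is.numeric(amplitude)) {
      rlang::abort("`amplitude` must be numeric or complex.", class = "holocyte_invalid_parameter")
    }
    amplitude <- amplitude + 0i
  }
  check_positive_scalar(pitch, "pitch")
  check_positive_scalar(wavelength, "wavelength")
  if (!is.numeric(z_ref) || length(z_ref) != 1 || !is.finite(z_ref)) {
    rlang::abort("`z_ref` must be a finite number.", class = "holocyte_invalid_parameter")
  }
  structure(
    list(amplitude = amplitude, pitch = pitch, wavelength = wavelength, z_ref = z_ref),
    class = "wave_field"
  )
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf(
    "<wave_field> %d x %d px, pitch %.3g um, lambda %.4g nm, z_ref %.5g um\n",
    nrow(x$amplitude), ncol(x$amplitude), x$pitch, x$wavelength, x$z_ref
  ))
  invisible(x)
}

#' Test for wave_field objects
#' @param x Object to test.
#' @return `TRUE` for `wave_field` objects.
#' @export
is_wave_field <- function(x) inherits(x, "wave_field")

#' Field intensity (squared modulus)
#' @param field A [wave_field()].
#' @return Numeric matrix of `|amplitude|^2`.
#' @export
intensity <- function(field) {
  stopifnot(is_wave_field(field))
  Mod(field$amplitude)^2
}

# shared argument checks -----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    rlang::abort(
      sprintf("`%s` must be a single positive finite number.", name),
      class = "holocyte_invalid_parameter"
    )
  }
  invisible(x)
}
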