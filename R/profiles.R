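#' Per-cell Z-axis optical signatures
#'
#' For every detected cell, evaluates the reconstructed complex field at
#' the cell centroid on a stack of planes about the focus plane `z0`:
#' `module = |field|`, `phase = arg(field)` (radians in `(-pi, pi]`, never
#' unwrapped). The default grid of 41 planes at 20 um spacing (+-400 um
#' about `z0`) is the cell's "optical signature" used by the downstream
#' gating.
#'
#' @param recon A `holo_recon` (or object-plane [wave_field()]); its
#'   `z_ref`/`z0_global` is the focus distance `z0`.
#' @param detections Tibble with `row`, `col` (e.g. from
#'   [confirm_detections()]). A detection whose centroid falls outside the
#'   frame is recorded with `NA` values rather than failing the whole stack.
#' @param z_half_range Half-span of the stack in micrometres (default 400).
#' @param z_step Plane spacing in micrometres (default 20; must divide
#'   `z_half_range`).
#' @param average_3x3 If `TRUE`, sample the 3x3 mean of the complex field
#'   instead of the single centroid pixel (off by default; the single-pixel
#'   signature is the canonical definition).
#' @return A tibble in long format: `cell_id`, `z_um` (distance from the
#'   sensor plane), `module`, `phase`; the focus distance is attached as
#'   attribute `"z0"`.
#' @export
compute_z_profiles <- function(recon, detections, z_half_range = 400, z_step = 20,
                               average_3x3 = FALSE) {
  field <- if (inherits(recon, "holo_recon")) recon$field else recon
  stopifnot(is_wave_field(field))
  check_positive_scalar(z_step, "z_step")
  if (abs(z_half_range / z_step - round(z_half_range / z_step)) > 1e-9) {
    rlang::abort("`z_half_range` must be a multiple of `z_step`.",
      class = "holocyte_invalid_parameter"
    )
  }
  z0 <- field$z_ref
  nr <- nrow(field$amplitude)
  nc <- ncol(field$amplitude)
  dzs <- seq(-z_half_range, z_half_range, by = z_step)
  n_det <- nrow(detections)
  if (!n_det) {
    out <- tibble::tibble(
      cell_id = integer(), z_um = double(),
      module = double(), phase = double()
    )
    attr(out, "z0") <- z0
    return(out)
  }

  inside <- detections$row >= 2 & detections$row <= nr - 1 &
    detections$col >= 2 & detections$col <= nc - 1
  vals <- matrix(NA_complex_, length(dzs), n_det)
  idx <- cbind(detections$row[inside], detections$col[inside])
  for (i in seq_along(dzs)) {
    A <- if (dzs[i] == 0) {
      field$amplitude
    } else {
      propagate_matrix(
        field$amplitude, field$pitch,
        field$wavelength * 1e-3, dzs[i],
        pad = TRUE
      )
    }
    vals[i, inside] <- if (average_3x3) {
      vapply(seq_len(nrow(idx)), function(k) {
        mean(A[(idx[k, 1] - 1):(idx[k, 1] + 1), (idx[k, 2] - 1):(idx[k, 2] + 1)])
      }, complex(1))
    } else {
      A[idx]
    }
  }

  out <- tibble::tibble(
    cell_id = rep(seq_len(n_det), each = length(dzs)),
    z_um = rep(z0 + dzs, times = n_det),
    module = as.vector(Mod(vals)),
    phase = as.vector(Arg(vals))
  )
  attr(out, "z0") <- z0
  out
}

#' Phase-profile amplitude
#'
#' The difference between the maximum and minimum of the phase values of a
#' Z-axis profile, computed without any phase unwrapping. A wrapped
#' discontinuity (values near +pi and -pi in one profile) therefore yields
#' an amplitude near 2*pi -- deliberately so: such cells exceed any sub-pi
#' gate and are classified as leukocytes.
#'
#' @param profile Tibble with a `phase` column (one cell's profile).
#' @return Amplitude in radians (0 for a constant profile).
#' @export
phase_amplitude <- function(profile) {
  ph <- profile$phase
  ph <- ph[is.finite(ph)]
  if (!length(ph)) {
    return(NA_real_)
  }
  max(ph) - min(ph)
}

#' Offset of the module-profile minimum from the focus plane
#'
#' Locates the interior local minimum of the module profile nearest `z0`
#' and returns its signed offset `zmin - z0` in micrometres. A profile with
#' no interior local minimum (monotone over the stack) returns `NA`, the
#' documented "no-minimum" sentinel; the module gate treats the sentinel as
#' an outlier.
#'
#' @param profile Tibble with `z_um` and `module` columns (one cell).
#' @param z0 Focus distance in micrometres (defaults to the profile
#'   attribute set by [compute_z_profiles()]).
#' @return Signed offset in micrometres, or `NA` if no interior minimum.
#' @export
module_minimum_offset <- function(profile, z0 = attr(profile, "z0")) {
  m <- profile$module
  z <- profile$z_um
  ok <- is.finite(m)
  m <- m[ok]
  z <- z[ok]
  n <- length(m)
  if (n < 3 || is.null(z0)) {
    return(NA_real_)
  }
  interior <- which(m[2:(n - 1)] <= m[1:(n - 2)] & m[2:(n - 1)] <= m[3:n]) + 1
  if (!length(interior)) {
    return(NA_real_)
  }
  zmin <- z[interior[which.min(abs(z[interior] - z0))]]
  zmin - z0
}

#' Per-cell features from a profile stack
#'
#' Maps [phase_amplitude()] and [module_minimum_offset()] over every cell of
#' a long profile table.
#'
#' @param profiles Long tibble from [compute_z_profiles()].
#' @return Tibble with one row per cell: `cell_id`, `z0`, `phase_amp`,
#'   `module_offset` (`NA` = no-minimum sentinel), `no_minimum`.
#' @export
profile_features <- function(profiles) {
  z0 <- attr(profiles, "z0")
  profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      off <- module_minimum_offset(df, z0 = z0)
      tibble::tibble(
        z0 = z0,
        phase_amp = phase_amplitude(df),
        module_offset = off,
        no_minimum = is.na(off)
      )
    }) |>
    dplyr::ungroup()
}
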