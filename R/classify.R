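#' Gating configuration
#'
#' Thresholds of the cell-classification gates and the specimen-level
#' decision rule.
#'
#' @param mode Gating mode: `"phase+module"` (default; the phase-amplitude
#'   gate with the module-profile outlier override), `"phase"`, or
#'   `"diameter"`.
#' @param diameter_threshold_px Diameter gate, pixels: larger than this ->
#'   leukocyte.
#' @param phase_threshold Phase-profile amplitude gate in radians, default
#'   1.38 (sometimes glossed as 80 degrees, which is arithmetically 1.396
#'   rad; the radian value is canonical here).
#' @param module_offset_threshold Module-profile gate, micrometres: a
#'   module minimum more than this far above the focus plane (or a missing
#'   interior minimum) marks an outlier profile -- typically a granular
#'   leukocyte -- and overrides the phase gate. Default 60 um (three
#'   stack steps): "well above" quantified.
#' @param erythrocyte_limit Erythrocyte concentration (cells/uL) at or
#'   above which a leukocyte-positive specimen is reclassified as
#'   haemorrhage. Default 4000.
#' @param leukocyte_cutoff Leukocyte concentration (cells/uL) defining
#'   pleocytosis/meningitis. Default 10.
#' @param inclusive Use `>=` at the leukocyte cutoff (default `TRUE`; the
#'   `>`-convention is available because the original wording is
#'   ambiguous).
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(mode = c("phase+module", "phase", "diameter"),
                          diameter_threshold_px = 5,
                          phase_threshold = 1.38,
                          module_offset_threshold = 60,
                          erythrocyte_limit = 4000,
                          leukocyte_cutoff = 10,
                          inclusive = TRUE) {
  mode <- match.arg(mode)
  for (nm in c(
    "diameter_threshold_px", "phase_threshold",
    "module_offset_threshold", "erythrocyte_limit", "leukocyte_cutoff"
  )) {
    check_positive_scalar(get(nm), nm)
  }
  structure(
    list(
      mode = mode,
      diameter_threshold_px = diameter_threshold_px,
      phase_threshold = phase_threshold,
      module_offset_threshold = module_offset_threshold,
      erythrocyte_limit = erythrocyte_limit,
      leukocyte_cutoff = leukocyte_cutoff,
      inclusive = inclusive
    ),
    class = "gating_config"
  )
}

#' Cell gates
#'
#' Each gate takes a per-cell tibble and returns it with a `label` column
#' (`"leukocyte"` / `"erythrocyte"`); [gate_module()] instead adds a logical
#' `module_override` column marking outlier module profiles that are forced
#' to leukocyte regardless of the phase gate.
#'
#' * `gate_diameter()`: diameter (pixels) greater than the threshold ->
#'   leukocyte. The reconstructed resolution makes this gate weak --
#'   erythrocytes (6-8 um) and small lymphocytes (7-8 um) overlap.
#' * `gate_phase()`: phase-profile amplitude greater than the threshold ->
#'   leukocyte. No unwrapping: wrapped discontinuities produce amplitudes
#'   near 2*pi and are (intentionally) gated as leukocytes.
#' * `gate_module()`: module-profile minimum well above the focus plane, or
#'   missing entirely (`NA` sentinel) -> outlier override.
#'
#' @param cells Per-cell tibble; needs `diameter_px` or `diameter_um` for
#'   the diameter gate, `phase_amp` for the phase gate, `module_offset` for
#'   the module gate.
#' @param threshold_px,phase_threshold,offset_threshold Gate thresholds.
#' @param pitch Pixel pitch (um) used to derive `diameter_px` from
#'   `diameter_um` when absent.
#' @return The input tibble with `label` (or `module_override`) added.
#' @export
gate_diameter <- function(cells, threshold_px = 5, pitch = 1.67) {
  d_px <- if ("diameter_px" %in% names(cells)) cells$diameter_px else cells$diameter_um / pitch
  dplyr::mutate(cells, label = ifelse(d_px > threshold_px, "leukocyte", "erythrocyte"))
}

#' @rdname gate_diameter
#' @export
gate_phase <- function(cells, phase_threshold = 1.38) {
  dplyr::mutate(cells,
    label = ifelse(.data$phase_amp > phase_threshold, "leukocyte", "erythrocyte")
  )
}

#' @rdname gate_diameter
#' @export
gate_module <- function(cells, offset_threshold = 60) {
  dplyr::mutate(cells,
    module_override = is.na(.data$module_offset) | .data$module_offset > offset_threshold
  )
}

#' Classify cells by the configured gating mode
#'
#' Applies the gates of [gating_config()]: the diameter-only mode, the
#' phase-amplitude mode, or the default phase gate with module-profile
#' outlier override. Every cell receives exactly one label, so leukocyte
#' and erythrocyte counts partition the detections.
#'
#' @param cells Per-cell feature tibble (see [gate_diameter()] for the
#'   columns each mode needs).
#' @param config A [gating_config()].
#' @param pitch Pixel pitch in micrometres (diameter mode).
#' @return `cells` with `label` (and `module_override` in the default mode).
#' @export
classify_cells <- function(cells, config = gating_config(), pitch = 1.67) {
  stopifnot(inherits(config, "gating_config"))
  switch(config$mode,
    "diameter" = gate_diameter(cells, config$diameter_threshold_px, pitch),
    "phase" = gate_phase(cells, config$phase_threshold),
    "phase+module" = {
      out <- gate_phase(cells, config$phase_threshold)
      out <- gate_module(out, config$module_offset_threshold)
      dplyr::mutate(out,
        label = ifelse(.data$module_override, "leukocyte", .data$label)
      )
    }
  )
}

#' Counts to concentration
#'
#' Converts a cell count observed in one frame into a concentration in
#' cells/uL: `count / (area_mm2 * depth_mm)` with 1 mm^3 = 1 uL. The frame
#' area uses side lengths rounded to 0.1 mm ([field_of_view_mm2()]), the
#' same arithmetic that gives the full sensor its 29.44 mm^2 field of view.
#'
#' @param count Non-negative cell count.
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param pitch Pixel pitch, micrometres.
#' @param chamber_depth_mm Chamber depth in millimetres (default 0.1).
#' @return Concentration in cells/uL.
#' @export
#' @examples
#' concentration(2944, c(3840, 2748), 1.67) # 1000 cells/uL
concentration <- function(count, frame_shape, pitch = 1.67, chamber_depth_mm = 0.1) {
  stopifnot(count >= 0)
  vol_ul <- field_of_view_mm2(frame_shape, pitch) * chamber_depth_mm
  count / vol_ul
}

#' Acquisition geometry constants
#'
#' `field_of_view_mm2()` is the frame area with each side rounded to
#' 0.1 mm (3840 x 2748 px at 1.67 um -> 6.4 mm x 4.6 mm = 29.44 mm^2);
#' `analyzed_volume_ul()` multiplies by the chamber depth and rounds to
#' whole microlitres (about 3 uL per acquisition for the full sensor).
#'
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param pitch Pixel pitch in micrometres.
#' @param round_mm Rounding unit for the side lengths (default 0.1 mm).
#' @return Area in mm^2 / volume in uL.
#' @export
field_of_view_mm2 <- function(frame_shape = c(3840, 2748), pitch = 1.67, round_mm = 0.1) {
  sides <- frame_shape * pitch * 1e-3
  if (round_mm > 0) sides <- round(sides / round_mm) * round_mm
  prod(sides)
}

#' @rdname field_of_view_mm2
#' @param chamber_depth_mm Chamber depth in millimetres.
#' @param digits Rounding for the reported volume (0 = whole uL).
#' @export
analyzed_volume_ul <- function(frame_shape = c(3840, 2748), pitch = 1.67,
                               chamber_depth_mm = 0.1, digits = 0) {
  round(field_of_view_mm2(frame_shape, pitch) * chamber_depth_mm, digits)
}

#' Specimen-level diagnostic call
#'
#' The decision rule: a specimen is called positive (meningitis) when the
#' leukocyte concentration reaches the pleocytosis cutoff (10 cells/uL)
#' AND the erythrocyte concentration stays below the haemorrhage limit
#' (4000 cells/uL). A specimen over both limits is negative with
#' `hemorrhage_flag = TRUE`: massive erythrocyte counts mark blood
#' contamination (haemorrhage / traumatic tap), where the leukocytes most
#' likely come from the blood rather than from meningeal inflammation.
#'
#' @param leuko_conc,ery_conc Concentrations in cells/uL.
#' @param config A [gating_config()]; `inclusive` selects `>=` (default) or
#'   `>` at the leukocyte cutoff.
#' @return One-row tibble: `call` (`"positive"`/`"negative"`),
#'   `hemorrhage_flag`.
#' @export
#' @examples
#' call_meningitis(15, 100)$call # positive
#' call_meningitis(15, 5000) # negative, flagged as haemorrhage
call_meningitis <- function(leuko_conc, ery_conc, config = gating_config()) {
  stopifnot(leuko_conc >= 0, ery_conc >= 0)
  # concentrations are count/volume ratios; allow for representation error
  # so that a mathematically-exact boundary value compares inclusively
  eps <- 1e-9
  over_cutoff <- if (config$inclusive) {
    leuko_conc >= config$leukocyte_cutoff * (1 - eps)
  } else {
    leuko_conc > config$leukocyte_cutoff * (1 + eps)
  }
  bloody <- ery_conc >= config$erythrocyte_limit * (1 - eps)
  tibble::tibble(
    call = ifelse(over_cutoff & !bloody, "positive", "negative"),
    hemorrhage_flag = over_cutoff & bloody
  )
}
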