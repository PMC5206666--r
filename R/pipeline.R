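#' Pipeline configuration
#'
#' Collects every tunable of the acquisition-to-call pipeline with the
#' geometry of the CSF instrument as defaults: 1.67 um pitch, 0.1 mm
#' chamber depth, object plane near 1000 um, LED band centres 625 / 527.5 /
#' 457.5 nm, detection on the blue channel and per-cell analysis on the red
#' channel, a 41-plane profile stack at 20 um spacing, and the gating
#' thresholds of [gating_config()] (1.38 rad, 60 um, 10 and 4000 cells/uL).
#'
#' @param pitch Pixel pitch, micrometres.
#' @param chamber_depth_mm Chamber depth, millimetres.
#' @param chamber_z Nominal object-plane distance, micrometres.
#' @param z_search Autofocus scan range `c(lo, hi)`, micrometres.
#' @param z_step Autofocus scan step, micrometres.
#' @param detection_channel,analysis_channel Channel names.
#' @param iterations Phase-retrieval iterations per channel.
#' @param detection_dz Detection defocus, micrometres.
#' @param detection Named list of [detect_cells()] parameters.
#' @param dip_min,dip_min_confirm In-focus module-dip confirmation
#'   thresholds for the detection and confirmation channels.
#' @param profile_half_range,profile_step Z-profile stack geometry,
#'   micrometres (defaults give 41 planes).
#' @param profile_average_3x3 Sample profiles as the 3x3 complex mean
#'   around the centroid instead of the single pixel. The pipeline enables
#'   this by default: at haemorrhage-level cell densities the single-pixel
#'   phasor picks up enough coherent neighbour/twin clutter to swing past
#'   +-pi and inflate the phase amplitude; the 3x3 mean suppresses that
#'   clutter while preserving the cell's own (spatially smooth) signature.
#' @param gating A [gating_config()].
#' @param seed Default seed for simulation commands.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pitch = 1.67,
                            chamber_depth_mm = 0.1,
                            chamber_z = 1000,
                            z_search = c(500, 1500),
                            z_step = 20,
                            detection_channel = "blue",
                            analysis_channel = "red",
                            iterations = 30,
                            detection_dz = 250,
                            detection = list(
                              radii = 2:10,
                              accumulator_threshold = 0.2,
                              edge_quantile = 0.90,
                              min_separation_px = 6,
                              margin_px = 12
                            ),
                            dip_min = 0.09,
                            dip_min_confirm = NULL,
                            profile_half_range = 400,
                            profile_step = 20,
                            profile_average_3x3 = TRUE,
                            gating = gating_config(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Simulate a complete specimen acquisition
#'
#' Samples a phantom scene and renders its three-channel hologram triplet.
#'
#' @param n_leukocytes,n_erythrocytes Ground-truth cell counts.
#' @param config A [pipeline_config()].
#' @param params A [phantom_params()]; frame/pitch/chamber defaults come
#'   from `config`.
#' @param seed Scene seed (defaults to `config$seed`).
#' @param noise Noise model passed to [simulate_rgb_acquisition()].
#' @param snr_db Signal-to-noise ratio for the Gaussian noise model.
#' @return List with `scene` and `holograms` (named red/green/blue).
#' @export
simulate_specimen <- function(n_leukocytes, n_erythrocytes,
                              config = pipeline_config(),
                              params = NULL, seed = config$seed,
                              noise = "gaussian", snr_db = 30) {
  if (is.null(params)) {
    params <- phantom_params(
      pitch = config$pitch,
      chamber_z = config$chamber_z
    )
  }
  scene <- sample_scene(n_leukocytes, n_erythrocytes, params, seed = seed)
  holos <- simulate_rgb_acquisition(scene, noise = noise, snr_db = snr_db)
  list(scene = scene, holograms = holos)
}

#' Analyse a hologram triplet and call the specimen
#'
#' The full pipeline: autofocus on the detection channel, phase retrieval
#' of the detection and analysis channels, circle-Hough detection on the
#' defocused module image with in-focus cross-channel confirmation,
#' per-cell Z-profiles on the analysis channel, gating classification,
#' conversion of counts to concentrations, and the meningitis decision
#' rule.
#'
#' A featureless acquisition (no focus found, e.g. a cell-free specimen)
#' yields an empty cell table and a negative call rather than an error.
#'
#' @param holograms Named list with at least the detection channel
#'   (`blue`) and, for profile gating, the analysis channel (`red`).
#' @param config A [pipeline_config()].
#' @return An object of class `specimen_result`: per-cell tibble `cells`,
#'   counts, concentrations (cells/uL), `call`, `hemorrhage_flag`,
#'   `z0`, `analyzed_volume_ul`, the config echo and stage timings.
#' @export
analyze_specimen <- function(holograms, config = pipeline_config()) {
  det_ch <- config$detection_channel
  ana_ch <- config$analysis_channel
  if (!det_ch %in% names(holograms)) {
    rlang::abort(sprintf("detection channel '%s' missing from holograms", det_ch))
  }
  h_det <- holograms[[det_ch]]
  h_ana <- holograms[[ana_ch]]
  frame_shape <- dim(h_det$intensity)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  af <- tryCatch(
    autofocus(h_det, config$z_search, config$z_step),
    holocyte_no_focus = function(e) NA_real_
  )
  timings["autofocus_s"] <- tic() - t0
  if (is.na(af[1])) {
    return(empty_specimen_result(frame_shape, config, timings))
  }
  # a crowded specimen can raise the sharpness metric on a spurious plane;
  # keep every prominent, well-separated local maximum as a candidate and
  # let the detection stage itself arbitrate (more confirmed cells wins)
  cand_z <- focus_candidates(attr(af, "focus_trace"), as.numeric(af))

  t0 <- tic()
  run_detection <- function(z0) {
    recon <- phase_retrieval(h_det, z0, iterations = config$iterations)
    dimg <- detection_image(recon, config$detection_dz)
    raw <- rlang::exec(detect_cells,
      image = dimg, pitch = config$pitch,
      !!!config$detection
    )
    dets <- confirm_detections(raw, recon,
      dip_min = config$dip_min,
      dip_min_confirm = config$dip_min_confirm,
      min_separation_px = config$detection$min_separation_px
    )
    list(z0 = z0, recon = recon, dets = dets)
  }
  trials <- lapply(cand_z, function(zc) {
    run_detection(refine_focus(h_det, zc, half_range = config$z_step))
  })
  best <- trials[[which.max(vapply(trials, function(tr) nrow(tr$dets), numeric(1)))]]
  z0 <- best$z0
  recon_det <- best$recon
  dets <- best$dets
  recon_ana <- if (!is.null(h_ana)) {
    phase_retrieval(h_ana, z0, iterations = config$iterations)
  }
  if (!is.null(recon_ana) && nrow(dets)) {
    # annotate (and optionally veto) against the analysis channel
    dets <- confirm_detections(dets, recon_det,
      recon_confirm = recon_ana,
      dip_min = config$dip_min,
      dip_min_confirm = config$dip_min_confirm,
      min_separation_px = config$detection$min_separation_px
    )
  }
  timings["detection_s"] <- tic() - t0

  t0 <- tic()
  prof_recon <- if (!is.null(recon_ana)) recon_ana else recon_det
  profiles <- compute_z_profiles(prof_recon, dets,
    z_half_range = config$profile_half_range,
    z_step = config$profile_step,
    average_3x3 = config$profile_average_3x3
  )
  feats <- profile_features(profiles)
  timings["profiles_s"] <- tic() - t0

  cells <- dplyr::bind_cols(dets, dplyr::select(feats, -"cell_id"))
  cells <- classify_cells(cells, config$gating, pitch = config$pitch)

  n_leu <- sum(cells$label == "leukocyte")
  n_ery <- sum(cells$label == "erythrocyte")
  leuko_conc <- concentration(n_leu, frame_shape, config$pitch, config$chamber_depth_mm)
  ery_conc <- concentration(n_ery, frame_shape, config$pitch, config$chamber_depth_mm)
  verdict <- call_meningitis(leuko_conc, ery_conc, config$gating)

  structure(
    list(
      cells = cells,
      profiles = profiles,
      n_leukocytes = n_leu,
      n_erythrocytes = n_ery,
      leuko_conc = leuko_conc,
      ery_conc = ery_conc,
      analyzed_volume_ul = field_of_view_mm2(frame_shape, config$pitch) * config$chamber_depth_mm,
      call = verdict$call,
      hemorrhage_flag = verdict$hemorrhage_flag,
      z0 = z0,
      frame_shape = frame_shape,
      config = config,
      timings = timings
    ),
    class = "specimen_result"
  )
}

# Prominent, well-separated interior local maxima of a focus trace.
focus_candidates <- function(trace, z_best, rel = 0.4, min_sep = 60, max_n = 2) {
  m <- trace$metric
  z <- trace$z
  n <- length(m)
  if (n < 3) {
    return(z_best)
  }
  lo <- min(m)
  prom <- m - lo
  is_max <- c(FALSE, m[2:(n - 1)] >= m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n], FALSE)
  cand <- z[is_max & prom >= rel * max(prom)]
  cand <- cand[order(-m[match(cand, z)])]
  keep <- z_best # the refined global optimum is always first
  for (zc in cand) {
    if (min(abs(keep - zc)) > min_sep) keep <- c(keep, zc)
    if (length(keep) >= max_n) break
  }
  utils::head(keep, max_n)
}

empty_specimen_result <- function(frame_shape, config, timings) {
  structure(
    list(
      cells = tibble::tibble(),
      profiles = tibble::tibble(),
      n_leukocytes = 0L,
      n_erythrocytes = 0L,
      leuko_conc = 0,
      ery_conc = 0,
      analyzed_volume_ul = field_of_view_mm2(frame_shape, config$pitch) * config$chamber_depth_mm,
      call = "negative",
      hemorrhage_flag = FALSE,
      z0 = NA_real_,
      frame_shape = frame_shape,
      config = config,
      timings = timings
    ),
    class = "specimen_result"
  )
}

#' @export
print.specimen_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<specimen_result> %d leukocytes (%.1f /uL), %d erythrocytes (%.1f /uL)\n",
      "  call: %s%s   volume %.3g uL, z0 %.4g um\n"
    ),
    x$n_leukocytes, x$leuko_conc, x$n_erythrocytes, x$ery_conc,
    x$call, if (x$hemorrhage_flag) " [hemorrhage]" else "",
    x$analyzed_volume_ul, x$z0
  ))
  invisible(x)
}

#' Per-cell table of a specimen result
#' @param x A `specimen_result`.
#' @param ... Unused.
#' @return The per-cell tibble (centroid, diameter, profile features,
#'   label).
#' @method tidy specimen_result
#' @export
tidy.specimen_result <- function(x, ...) x$cells

#' One-row summary of a specimen result
#' @param x A `specimen_result`.
#' @param ... Unused.
#' @return One-row tibble with counts, concentrations, volume, call and
#'   haemorrhage flag.
#' @method glance specimen_result
#' @export
glance.specimen_result <- function(x, ...) {
  tibble::tibble(
    n_leukocytes = x$n_leukocytes,
    n_erythrocytes = x$n_erythrocytes,
    leuko_conc = x$leuko_conc,
    ery_conc = x$ery_conc,
    analyzed_volume_ul = x$analyzed_volume_ul,
    call = x$call,
    hemorrhage_flag = x$hemorrhage_flag,
    z0 = x$z0
  )
}

#' Write a specimen report as JSON / per-cell CSV
#'
#' @param result A `specimen_result`.
#' @param json_path,cells_path Output paths (either may be `NULL`).
#' @return `result`, invisibly.
#' @export
write_specimen_report <- function(result, json_path = NULL, cells_path = NULL) {
  stopifnot(inherits(result, "specimen_result"))
  if (!is.null(cells_path) && nrow(result$cells)) {
    readr::write_csv(result$cells, cells_path)
  }
  if (!is.null(json_path)) {
    cfg <- result$config
    report <- list(
      n_leukocytes = result$n_leukocytes,
      n_erythrocytes = result$n_erythrocytes,
      leuko_conc_per_ul = result$leuko_conc,
      ery_conc_per_ul = result$ery_conc,
      analyzed_volume_ul = result$analyzed_volume_ul,
      call = result$call,
      hemorrhage_flag = result$hemorrhage_flag,
      z0_um = result$z0,
      frame_shape = result$frame_shape,
      config = list(
        pitch_um = cfg$pitch,
        chamber_depth_mm = cfg$chamber_depth_mm,
        detection_channel = cfg$detection_channel,
        analysis_channel = cfg$analysis_channel,
        iterations = cfg$iterations,
        detection_dz_um = cfg$detection_dz,
        phase_threshold_rad = cfg$gating$phase_threshold,
        module_offset_threshold_um = cfg$gating$module_offset_threshold,
        leukocyte_cutoff_per_ul = cfg$gating$leukocyte_cutoff,
        erythrocyte_limit_per_ul = cfg$gating$erythrocyte_limit
      ),
      timings_s = as.list(result$timings)
    )
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
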