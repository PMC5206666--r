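#' Phantom generation parameters
#'
#' Bundles the acquisition geometry and the per-kind cell property ranges
#' used by [sample_scene()]. Defaults emulate the CSF acquisition geometry:
#' 1.67 um pixel pitch, a 0.1 mm deep counting chamber sitting on the
#' sensor with its object plane about 1000 um above the sensor, and cells
#' drawn as thin phase/absorption disks.
#'
#' Cell property ranges:
#' * diameters: erythrocytes 6-8 um, leukocytes 7-30 um;
#' * peak phase delay (at the 625 nm reference wavelength): erythrocytes
#'   0.5-1.2 rad, leukocytes 1.6-3.5 rad, so that the two classes straddle
#'   the 1.38 rad phase-amplitude gate;
#' * absorption: erythrocytes 0.35-0.6 (haemoglobin absorbs strongly at the
#'   blue end of the visible spectrum, which is part of why the blue channel
#'   is the detection channel), leukocytes 0.05-0.15 (largely transparent
#'   phase objects).
#'
#' @param frame_shape Integer vector `c(rows, cols)` in pixels. The full
#'   sensor is 3840 x 2748; the default 512 x 512 is a desk-scale crop.
#' @param pitch Pixel pitch in micrometres.
#' @param chamber_z Object-plane distance from the sensor in micrometres.
#' @param min_sep_um Minimum centre-to-centre distance between cells.
#' @param margin_px Cells are placed at least this many pixels from the
#'   frame edge.
#' @param leu_diameter,ery_diameter Diameter ranges, micrometres.
#' @param leu_phase,ery_phase Peak-phase ranges at 625 nm, radians.
#' @param leu_absorption,ery_absorption Absorption fraction ranges in `[0, 1)`,
#'   quoted at the blue (457.5 nm) channel.
#' @param ery_absorption_spectrum,leu_absorption_spectrum Named multipliers
#'   (`blue`, `green`, `red`) applied to the per-cell absorption when
#'   rendering each channel. The erythrocyte default (1, 0.6, 0.2) follows
#'   the haemoglobin absorption spectrum -- strong towards the Soret band,
#'   weak in the red -- which is what makes the blue channel the natural
#'   detection channel and leaves the red channel's per-cell phase
#'   signatures clean; leukocytes are spectrally flat.
#' @param z_jitter_um Optional per-cell axial jitter (<= chamber depth,
#'   100 um); 0 keeps all cells coplanar.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(frame_shape = c(512L, 512L),
                           pitch = 1.67,
                           chamber_z = 1000,
                           min_sep_um = 25,
                           margin_px = 20,
                           leu_diameter = c(7, 30),
                           ery_diameter = c(6, 8),
                           leu_phase = c(1.6, 3.5),
                           ery_phase = c(0.5, 1.2),
                           leu_absorption = c(0.05, 0.15),
                           ery_absorption = c(0.35, 0.6),
                           ery_absorption_spectrum = c(blue = 1, green = 0.6, red = 0.2),
                           leu_absorption_spectrum = c(blue = 1, green = 1, red = 1),
                           z_jitter_um = 0) {
  check_positive_scalar(pitch, "pitch")
  check_positive_scalar(chamber_z, "chamber_z")
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 32))
  structure(as.list(environment()), class = "phantom_params")
}

#' Sample a synthetic CSF scene with ground truth
#'
#' Draws cell centres uniformly over the frame (respecting a minimum
#' centre-to-centre distance and an edge margin) and per-kind diameters,
#' peak phases and absorptions from the ranges in [phantom_params()].
#' Reproducible for a fixed seed. The returned scene carries its full
#' ground truth; downstream recovery tests (detection recall,
#' classification accuracy, concentrations) are evaluated against it.
#'
#' @param n_leukocytes,n_erythrocytes Non-negative cell counts.
#' @param params A [phantom_params()] list.
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `phantom_scene`: list with `cells` (a tibble
#'   with one row per cell: kind, row_px, col_px, diameter_um, peak_phase,
#'   absorption, z_um), `chamber_z`, `frame_shape`, `pitch`, `seed`.
#' @export
#' @examples
#' sc <- sample_scene(2, 10, phantom_params(frame_shape = c(128, 128)), seed = 1)
#' sc$cells
sample_scene <- function(n_leukocytes, n_erythrocytes, params = phantom_params(), seed) {
  stopifnot(
    inherits(params, "phantom_params"),
    n_leukocytes >= 0, n_erythrocytes >= 0
  )
  if (missing(seed)) rlang::abort("`seed` is required for a reproducible scene.")
  n <- n_leukocytes + n_erythrocytes
  nr <- params$frame_shape[1]
  nc <- params$frame_shape[2]
  set.seed(as.integer(seed))

  kind <- c(rep("leukocyte", n_leukocytes), rep("erythrocyte", n_erythrocytes))
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  max_tries <- max(20000L, 200L * n)
  while (nrow(pts) < n && tries < max_tries) {
    p <- c(
      stats::runif(1, params$margin_px, nr - params$margin_px),
      stats::runif(1, params$margin_px, nc - params$margin_px)
    )
    if (nrow(pts) == 0 ||
      min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) * params$pitch >= params$min_sep_um) {
      pts <- rbind(pts, p)
    }
    tries <- tries + 1L
  }
  if (nrow(pts) < n) {
    rlang::abort(
      sprintf(
        "could not place %d cells with min separation %g um in a %d x %d frame",
        n, params$min_sep_um, nr, nc
      ),
      class = "holocyte_packing_error"
    )
  }

  draw <- function(k, rng_leu, rng_ery) {
    lo <- ifelse(k == "leukocyte", rng_leu[1], rng_ery[1])
    hi <- ifelse(k == "leukocyte", rng_leu[2], rng_ery[2])
    stats::runif(length(k), lo, hi)
  }
  cells <- tibble::tibble(
    kind = kind,
    row_px = pts[, 1],
    col_px = pts[, 2],
    diameter_um = draw(kind, params$leu_diameter, params$ery_diameter),
    peak_phase = draw(kind, params$leu_phase, params$ery_phase),
    absorption = draw(kind, params$leu_absorption, params$ery_absorption),
    z_um = params$chamber_z +
      if (params$z_jitter_um > 0) stats::runif(length(kind), 0, params$z_jitter_um) else 0
  )
  structure(
    list(
      cells = cells, chamber_z = params$chamber_z,
      frame_shape = as.integer(params$frame_shape), pitch = params$pitch,
      seed = as.integer(seed), params = params
    ),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d leukocytes + %d erythrocytes in %d x %d px, chamber_z %g um, seed %d\n",
    sum(x$cells$kind == "leukocyte"), sum(x$cells$kind == "erythrocyte"),
    x$frame_shape[1], x$frame_shape[2], x$chamber_z, x$seed
  ))
  invisible(x)
}

#' Ground-truth cell concentrations of a scene
#'
#' Counts divided by the analysed volume of the scene's frame (frame area at
#' the stated pitch times the 0.1 mm chamber depth), using the same
#' [concentration()] arithmetic as the recovery pipeline.
#'
#' @param scene A [sample_scene()] result.
#' @param chamber_depth_mm Chamber depth in millimetres.
#' @return A tibble with `leuko_conc` and `ery_conc` in cells/uL.
#' @export
scene_concentrations <- function(scene, chamber_depth_mm = 0.1) {
  stopifnot(inherits(scene, "phantom_scene"))
  tibble::tibble(
    leuko_conc = concentration(
      sum(scene$cells$kind == "leukocyte"),
      scene$frame_shape, scene$pitch, chamber_depth_mm
    ),
    ery_conc = concentration(
      sum(scene$cells$kind == "erythrocyte"),
      scene$frame_shape, scene$pitch, chamber_depth_mm
    )
  )
}

#' Thin-object transmittance of a scene
#'
#' Renders the scene as a complex transmittance
#' `t(x, y) = (1 - absorption_total) * exp(i * phi_total)` where each cell
#' contributes a raised-cosine radial cap peaking at its `peak_phase`
#' (phases of overlapping cells add; absorptions accumulate and are capped
#' below 1). Phase delays scale with the wavelength ratio `625 / lambda`
#' (the phase ranges are quoted at the 625 nm red reference), as for a fixed
#' optical path difference.
#'
#' @param scene A [sample_scene()] result.
#' @param wavelength Wavelength in nanometres.
#' @return A [wave_field()] at the object plane (`z_ref = chamber_z`).
#' @export
render_transmittance <- function(scene, wavelength) {
  stopifnot(inherits(scene, "phantom_scene"))
  check_positive_scalar(wavelength, "wavelength")
  nr <- scene$frame_shape[1]
  nc <- scene$frame_shape[2]
  phi <- matrix(0, nr, nc)
  absb <- matrix(0, nr, nc)
  scale <- 625 / wavelength
  chan <- wavelength_channel(wavelength)
  pars <- scene$params
  abs_w <- function(kind) {
    spec <- if (kind == "leukocyte") pars$leu_absorption_spectrum else pars$ery_absorption_spectrum
    if (is.null(spec) || !chan %in% names(spec)) 1 else unname(spec[chan])
  }
  cells <- scene$cells
  for (k in seq_len(nrow(cells))) {
    rad_px <- cells$diameter_um[k] / 2 / scene$pitch
    r0 <- cells$row_px[k]
    c0 <- cells$col_px[k]
    ri <- max(1, floor(r0 - rad_px - 1)):min(nr, ceiling(r0 + rad_px + 1))
    ci <- max(1, floor(c0 - rad_px - 1)):min(nc, ceiling(c0 + rad_px + 1))
    D <- sqrt(outer((ri - r0)^2, rep(1, length(ci))) + outer(rep(1, length(ri)), (ci - c0)^2))
    cap <- 0.5 * (1 + cos(pi * pmin(D / rad_px, 1)))
    phi[ri, ci] <- phi[ri, ci] + cells$peak_phase[k] * scale * cap
    absb[ri, ci] <- pmin(absb[ri, ci] + abs_w(cells$kind[k]) * cells$absorption[k] * cap, 0.99)
  }
  wave_field((1 - absb) * exp(1i * phi), scene$pitch, wavelength, z_ref = scene$chamber_z)
}

#' Simulate an in-line hologram of a scene
#'
#' Forward model: the object-plane transmittance under unit plane-wave
#' illumination is propagated to the sensor plane with [propagate()], the
#' intensity `|field|^2` is scaled to sensor counts, sensor noise is applied,
#' and the result is clipped to the non-negative 16-bit integer range. When
#' the scene has per-cell axial jitter the transmittance is rendered and
#' propagated slice by slice (multiplicative thin slices, furthest from the
#' sensor first).
#'
#' @param scene A [sample_scene()] result.
#' @param wavelength Wavelength in nanometres.
#' @param noise One of `"gaussian"` (additive, default), `"none"`, `"shot"`
#'   (Poisson with `photon_budget` expected counts per pixel).
#' @param snr_db Signal-to-noise ratio in dB for the Gaussian model
#'   (`sigma = mean(I) / 10^(snr_db / 20)`; the 30 dB default is an
#'   arbitrary but plausible sensor figure).
#' @param photon_budget Mean photon count per pixel for the shot model.
#' @param counts_scale Sensor counts corresponding to the mean background
#'   intensity.
#' @param seed Optional integer seed for the noise draw (defaults to the
#'   scene seed plus a channel-dependent offset in
#'   [simulate_rgb_acquisition()]).
#' @return A [hologram()].
#' @export
simulate_hologram <- function(scene, wavelength,
                              noise = c("gaussian", "none", "shot"),
                              snr_db = 30, photon_budget = 10000,
                              counts_scale = 10000, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(scene, "phantom_scene"))
  zs <- sort(unique(round(scene$cells$z_um, 6)), decreasing = TRUE)
  if (length(zs) <= 1) {
    t_obj <- render_transmittance(scene, wavelength)
    sensor <- propagate(t_obj, -scene$chamber_z, pad = TRUE)
  } else {
    # multi-slice: accumulate the field downwards through the jittered planes
    field <- NULL
    z_prev <- NULL
    for (z in zs) {
      sub <- scene
      sub$cells <- scene$cells[abs(scene$cells$z_um - z) < 1e-6, , drop = FALSE]
      sub$chamber_z <- z
      t_sl <- render_transmittance(sub, wavelength)
      if (is.null(field)) {
        field <- t_sl
      } else {
        field <- propagate(field, z - z_prev, pad = TRUE)
        field$amplitude <- field$amplitude * t_sl$amplitude
      }
      z_prev <- z
    }
    sensor <- propagate(field, -z_prev, pad = TRUE)
  }
  I <- Mod(sensor$amplitude)^2
  I <- I / mean(I) * counts_scale
  if (noise != "none") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    I <- switch(noise,
      gaussian = I + stats::rnorm(length(I), 0, mean(I) / 10^(snr_db / 20)),
      shot = counts_scale / photon_budget *
        stats::rpois(length(I), I / counts_scale * photon_budget)
    )
    I <- matrix(I, nrow(sensor$amplitude), ncol(sensor$amplitude))
  }
  I <- pmin(pmax(round(I), 0), 65535)
  chan <- wavelength_channel(wavelength)
  hologram(I, pitch = scene$pitch, wavelength = wavelength, channel = chan)
}

#' Simulate the sequential red/green/blue acquisition
#'
#' Wraps [simulate_hologram()] at the band-centre wavelengths of the three
#' LED bands (620-630 -> 625, 520-535 -> 527.5, 450-465 -> 457.5 nm); same
#' scene, independent noise draws per channel (deterministic given the scene
#' seed).
#'
#' @inheritParams simulate_hologram
#' @return A named list of three [hologram()]s: `red`, `green`, `blue`.
#' @export
simulate_rgb_acquisition <- function(scene, noise = c("gaussian", "none", "shot"),
                                     snr_db = 30, photon_budget = 10000,
                                     counts_scale = 10000) {
  noise <- match.arg(noise)
  wl <- channel_wavelengths()
  out <- lapply(seq_along(wl), function(k) {
    simulate_hologram(scene, wl[[k]],
      noise = noise, snr_db = snr_db,
      photon_budget = photon_budget, counts_scale = counts_scale,
      seed = scene$seed + 101L * k
    )
  })
  names(out) <- names(wl)
  out
}

#' Band-centre wavelengths of the three illumination channels
#' @return Named numeric vector (nm): red 625, green 527.5, blue 457.5.
#' @export
channel_wavelengths <- function() {
  c(red = 625, green = 527.5, blue = 457.5)
}

wavelength_channel <- function(wavelength) {
  wl <- channel_wavelengths()
  names(wl)[which.min(abs(wl - wavelength))]
}
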