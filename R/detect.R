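#' Defocused module image for detection
#'
#' Module (magnitude) of the reconstructed field propagated by `dz`. Cell
#' detection runs on a deliberately defocused module image: defocusing by
#' a couple of hundred micrometres turns each cell into a circular
#' diffraction pattern whose rings the circle-Hough transform picks up
#' efficiently.
#'
#' @param recon A `holo_recon` from [phase_retrieval()], or a
#'   [wave_field()] at the object plane.
#' @param dz Defocus in micrometres (default +250, away from the sensor).
#' @return Numeric matrix (module image).
#' @export
detection_image <- function(recon, dz = 250) {
  field <- if (inherits(recon, "holo_recon")) recon$field else recon
  stopifnot(is_wave_field(field))
  if (!is.numeric(dz) || length(dz) != 1 || !is.finite(dz)) {
    rlang::abort("`dz` must be finite.", class = "holocyte_invalid_parameter")
  }
  Mod(propagate(field, dz, pad = TRUE)$amplitude)
}

#' Circle-Hough cell detection on a module image
#'
#' Gradient-oriented circular Hough transform. The image is lightly
#' smoothed, the gradient magnitude is thresholded at `edge_quantile` to
#' form the edge set, and every edge pixel casts one vote per candidate
#' radius at the two points along its gradient direction (dark-centre and
#' bright-centre circles both vote). Per-radius accumulators are smoothed
#' and normalised by the circle circumference, so the score is
#' approximately the fraction of the perimeter supported by edges; the
#' radius with the best score wins per pixel. Peaks are local maxima in a
#' 5x5 neighbourhood above `accumulator_threshold`, returned in descending
#' score order with duplicates inside `min_separation_px` suppressed
#' (higher score kept).
#'
#' A constant (blank) image returns an empty table, not an error. Detection
#' is deterministic for a fixed input and parameter set, and the number of
#' detections is monotone non-increasing in `accumulator_threshold`.
#'
#' @param image Module image (numeric matrix), typically from
#'   [detection_image()].
#' @param radii Candidate circle radii in pixels (default 2:10, covering
#'   ~6-32 um diameters at 1.67 um pitch).
#' @param accumulator_threshold Minimum perimeter-coverage score for a peak.
#' @param edge_quantile Gradient-magnitude quantile defining the edge set.
#' @param min_separation_px Minimum distance between kept detections.
#' @param margin_px Frame margin excluded from edges and peaks (reconstruction
#'   borders carry wrap-around artefacts).
#' @param pitch Pixel pitch in micrometres, used to convert radii to
#'   diameters.
#' @return Tibble with one row per detection: `row`, `col` (1-based pixel
#'   centroids), `radius_px`, `diameter_um` (`2 * radius_px * pitch`),
#'   `score`.
#' @export
detect_cells <- function(image, radii = 2:10, accumulator_threshold = 0.3,
                         edge_quantile = 0.90, min_separation_px = 6,
                         margin_px = 12, pitch = 1.67) {
  stopifnot(is.matrix(image), is.numeric(image))
  nr <- nrow(image)
  nc <- ncol(image)
  empty <- tibble::tibble(
    row = integer(), col = integer(), radius_px = integer(),
    diameter_um = double(), score = double()
  )
  if (nr < 2 * margin_px + 8 || nc < 2 * margin_px + 8) {
    return(empty)
  }

  M <- smooth3(image)
  gr <- M * 0
  gc <- M * 0
  gr[2:(nr - 1), ] <- (M[3:nr, ] - M[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (M[, 3:nc] - M[, 1:(nc - 2)]) / 2
  G <- sqrt(gr^2 + gc^2)
  mask <- matrix(FALSE, nr, nc)
  mask[(margin_px + 1):(nr - margin_px), (margin_px + 1):(nc - margin_px)] <- TRUE
  G[!mask] <- 0
  if (max(G) - min(G) < 1e-12 || max(G) < 1e-12 * max(abs(M), 1)) {
    return(empty) # featureless image: no edges, no circles
  }
  thr <- stats::quantile(G[mask], edge_quantile)
  ei <- which(G >= thr & G > 0)
  if (!length(ei)) {
    return(empty)
  }
  er <- (ei - 1) %% nr + 1
  ec <- (ei - 1) %/% nr + 1
  ur <- gr[ei] / G[ei]
  uc <- gc[ei] / G[ei]

  best <- matrix(0, nr, nc)
  bestr <- matrix(NA_integer_, nr, nc)
  for (r in radii) {
    A <- matrix(0, nr, nc)
    for (sgn in c(-1, 1)) {
      vr <- round(er + sgn * r * ur)
      vc <- round(ec + sgn * r * uc)
      ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
      if (!any(ok)) next
      tb <- rowsum(rep(1, sum(ok)), group = (vc[ok] - 1) * nr + vr[ok])
      A[as.integer(rownames(tb))] <- A[as.integer(rownames(tb))] + tb[, 1]
    }
    A <- smooth3(A) * 9 / (2 * pi * r) # 3x3 vote pooling / circumference
    upd <- A > best
    best[upd] <- A[upd]
    bestr[upd] <- r
  }
  best[!mask] <- 0

  is_peak <- best >= accumulator_threshold & local_maxima5(best)
  cand <- which(is_peak)
  if (!length(cand)) {
    return(empty)
  }
  cand <- cand[order(best[cand], decreasing = TRUE)]
  rows <- (cand - 1) %% nr + 1
  cols <- (cand - 1) %/% nr + 1
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(keep) ||
      min((rows[keep] - rows[i])^2 + (cols[keep] - cols[i])^2) > min_separation_px^2) {
      keep[i] <- TRUE
    }
  }
  tibble::tibble(
    row = rows[keep],
    col = cols[keep],
    radius_px = bestr[cand[keep]],
    diameter_um = 2 * bestr[cand[keep]] * pitch,
    score = best[cand[keep]]
  )
}

#' Confirm and refine Hough candidates against in-focus reconstructions
#'
#' Each candidate centre is refined to the local minimum of the in-focus
#' module image within `refine_px` pixels (cells appear as compact dark
#' disks at focus), then verified by requiring a 3x3-mean module dip of at
#' least `dip_min` below the background median -- in the detection channel
#' and, when a second reconstruction is supplied, in that channel too.
#' Cross-channel confirmation is a strong clutter filter: residual
#' twin-image ghost rings sit at wavelength-dependent radii around strong
#' scatterers, while genuine cells coincide across channels. The diameter
#' is re-estimated from the full width at half depth of the in-focus radial
#' dip profile.
#'
#' @param detections Tibble from [detect_cells()].
#' @param recon Detection-channel reconstruction (`holo_recon` or
#'   [wave_field()]) at the object plane.
#' @param recon_confirm Optional second-channel reconstruction for
#'   cross-channel confirmation.
#' @param dip_min Minimum 3x3-mean module dip below background in the
#'   detection channel.
#' @param dip_min_confirm Optional veto threshold for the confirmation
#'   channel (`NULL`, the default, records the confirmation dip without
#'   vetoing). A cell can legitimately be faint in the second channel --
#'   erythrocytes barely absorb red light -- so the cross-channel dip is
#'   annotation first, filter only on request.
#' @param refine_px Centre-refinement search radius in pixels.
#' @param min_separation_px Post-refinement duplicate suppression distance.
#' @param z_bracket_um Offsets (micrometres) about the focus plane over
#'   which the dip is evaluated; the per-candidate maximum over the bracket
#'   is used. The in-focus dip of a micron-scale cell decays within tens of
#'   micrometres of defocus, so a small bracket absorbs the residual
#'   autofocus error (and per-cell axial jitter within the chamber).
#' @return Tibble like `detections` with refined `row`, `col`,
#'   `diameter_um`, plus `dip` (and `dip_confirm` when a second channel is
#'   given).
#' @export
confirm_detections <- function(detections, recon, recon_confirm = NULL,
                               dip_min = 0.09, dip_min_confirm = NULL,
                               refine_px = 4, min_separation_px = 6,
                               z_bracket_um = seq(-20, 20, by = 10)) {
  field <- if (inherits(recon, "holo_recon")) recon$field else recon
  pitch <- field$pitch
  stack_of <- function(f) {
    lapply(z_bracket_um, function(dz) {
      M <- if (dz == 0) {
        Mod(f$amplitude)
      } else {
        Mod(propagate(f, dz, pad = TRUE)$amplitude)
      }
      smooth3(M) # centre refinement tracks the smoothed dip, not pixel noise
    })
  }
  Ms <- stack_of(field)
  Mcs <- if (!is.null(recon_confirm)) {
    f2 <- if (inherits(recon_confirm, "holo_recon")) recon_confirm$field else recon_confirm
    stack_of(f2)
  }
  bgs <- vapply(Ms, stats::median, numeric(1))
  bgcs <- if (!is.null(Mcs)) vapply(Mcs, stats::median, numeric(1))
  nr <- nrow(Ms[[1]])
  nc <- ncol(Ms[[1]])

  if (!nrow(detections)) {
    out <- detections
    out$dip <- double()
    if (!is.null(Mcs)) out$dip_confirm <- double()
    return(out)
  }

  # per-plane dip of the 3x3 mean at (r, c)
  dip_at <- function(stack, bg_vec, rr, cc) {
    vapply(seq_along(stack), function(k) {
      bg_vec[k] - mean(stack[[k]][(rr - 1):(rr + 1), (cc - 1):(cc + 1)])
    }, numeric(1))
  }

  rows <- integer(0)
  cols <- integer(0)
  dips <- double(0)
  dips2 <- double(0)
  diam <- double(0)
  kept <- integer(0)
  for (i in seq_len(nrow(detections))) {
    r0 <- detections$row[i]
    c0 <- detections$col[i]
    rs <- max(2, r0 - refine_px):min(nr - 1, r0 + refine_px)
    cs <- max(2, c0 - refine_px):min(nc - 1, c0 + refine_px)
    # refine on the bracket plane with the deepest local minimum
    best_plane <- 1L
    best_val <- Inf
    rr <- r0
    cc <- c0
    for (k in seq_along(Ms)) {
      sub <- Ms[[k]][rs, cs]
      mi <- which.min(sub)
      if (sub[mi] - bgs[k] < best_val) {
        best_val <- sub[mi] - bgs[k]
        best_plane <- k
        rr <- rs[(mi - 1) %% length(rs) + 1]
        cc <- cs[(mi - 1) %/% length(rs) + 1]
      }
    }
    dip <- max(dip_at(Ms, bgs, rr, cc))
    if (dip < dip_min) next
    if (!is.null(Mcs)) {
      dip2 <- max(dip_at(Mcs, bgcs, rr, cc))
      if (!is.null(dip_min_confirm) && dip2 < dip_min_confirm) next
      dips2 <- c(dips2, dip2)
    }
    rows <- c(rows, rr)
    cols <- c(cols, cc)
    dips <- c(dips, dip)
    diam <- c(diam, dip_fwhm_diameter(
      Ms[[best_plane]], rr, cc, bgs[best_plane],
      pitch
    ))
    kept <- c(kept, i)
  }
  out <- detections[kept, , drop = FALSE]
  out$row <- rows
  out$col <- cols
  out$diameter_um <- diam
  out$dip <- dips
  if (!is.null(Mcs)) out$dip_confirm <- dips2

  if (nrow(out) > 1) {
    # refinement can merge neighbouring candidates onto one minimum
    out <- dplyr::arrange(out, dplyr::desc(.data$dip))
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      d2 <- (out$row[seq_len(i - 1)] - out$row[i])^2 + (out$col[seq_len(i - 1)] - out$col[i])^2
      if (any(keep[seq_len(i - 1)] & d2 <= min_separation_px^2)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  dplyr::arrange(out, dplyr::desc(.data$score))
}

# Diameter from the full width at half depth of the radial dip profile of
# the in-focus module image around (r0, c0).
dip_fwhm_diameter <- function(M, r0, c0, bg, pitch, r_max = 12) {
  nr <- nrow(M)
  nc <- ncol(M)
  radii <- 0:r_max
  prof <- vapply(radii, function(rr) {
    if (rr == 0) {
      return(bg - M[r0, c0])
    }
    th <- seq(0, 2 * pi, length.out = max(8, ceiling(2 * pi * rr)) + 1)[-1]
    pr <- pmin(pmax(round(r0 + rr * cos(th)), 1), nr)
    pc <- pmin(pmax(round(c0 + rr * sin(th)), 1), nc)
    bg - mean(M[cbind(pr, pc)])
  }, numeric(1))
  half <- prof[1] / 2
  if (prof[1] <= 0) {
    return(2 * pitch)
  }
  below <- which(prof <= half)
  below <- below[below > 1]
  if (!length(below)) {
    return(2 * r_max * pitch)
  }
  i <- below[1]
  # linear interpolation between the last sample above and first below half
  frac <- (prof[i - 1] - half) / (prof[i - 1] - prof[i])
  r_half <- radii[i - 1] + frac * (radii[i] - radii[i - 1])
  2 * r_half * pitch
}

smooth3 <- function(A) {
  n <- nrow(A)
  m <- ncol(A)
  if (n < 3 || m < 3) {
    return(A)
  }
  B <- A
  B[2:(n - 1), 2:(m - 1)] <-
    (A[1:(n - 2), 1:(m - 2)] + A[1:(n - 2), 2:(m - 1)] + A[1:(n - 2), 3:m] +
      A[2:(n - 1), 1:(m - 2)] + A[2:(n - 1), 2:(m - 1)] + A[2:(n - 1), 3:m] +
      A[3:n, 1:(m - 2)] + A[3:n, 2:(m - 1)] + A[3:n, 3:m]) / 9
  B
}

local_maxima5 <- function(A) {
  n <- nrow(A)
  m <- ncol(A)
  out <- matrix(TRUE, n, m)
  for (dr in -2:2) {
    for (dc in -2:2) {
      if (dr == 0 && dc == 0) next
      S <- matrix(-Inf, n, m)
      rs <- max(1, 1 + dr):min(n, n + dr)
      cs <- max(1, 1 + dc):min(m, m + dc)
      S[rs - dr, cs - dc] <- A[rs, cs]
      out <- out & (A >= S)
    }
  }
  out
}
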