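#' Back-propagate a hologram to the object plane
#'
#' Treats the square root of the recorded intensity as a real-valued field
#' at the sensor plane (normalised by its median so that the background
#' sits near unit modulus) and propagates it back by `-z`. The result
#' carries the twin-image artefact by construction: the missing phase means
#' the conjugate, out-of-focus copy of every object is superimposed on the
#' true image. [phase_retrieval()] suppresses it.
#'
#' @param h A [hologram()].
#' @param z Object-plane distance from the sensor, micrometres (> 0).
#' @return A [wave_field()] at the object plane (`z_ref = z`).
#' @export
backpropagate <- function(h, z) {
  stopifnot(is_hologram(h))
  if (!is.numeric(z) || length(z) != 1 || !is.finite(z) || z <= 0) {
    rlang::abort("`z` must be a single positive distance in um.", class = "holocyte_invalid_parameter")
  }
  a <- sqrt(h$intensity)
  med <- stats::median(a)
  if (med > 0) a <- a / med
  sensor <- wave_field(a + 0i, h$pitch, h$wavelength, z_ref = 0)
  # the sensor field travelled -z to reach the sensor; undo it with +z
  out <- propagate(sensor, +z, pad = TRUE)
  out$amplitude <- remove_piston(out$amplitude)
  out
}

# Rotate a field so its background (mean phasor) phase is zero. The
# absolute (piston) phase of a reconstruction depends on z0 modulo the
# wavelength and is physically unobservable; left in place it can park the
# background near +-pi, where every small per-cell excursion wraps.
remove_piston <- function(A) {
  phi <- Arg(mean(A))
  if (is.finite(phi) && phi != 0) A * exp(-1i * phi) else A
}

#' Autofocus: estimate the object-plane distance
#'
#' Scans back-propagation distances over `z_range` and returns the distance
#' maximising a sharpness metric of the module image, refined by parabolic
#' interpolation around the grid optimum.
#'
#' The default metric is the kurtosis of the module image's deviation from
#' its median: at focus a sparse scene concentrates its contrast into
#' compact cells (heavy-tailed deviation, high kurtosis), while away from
#' focus the same energy spreads into low-contrast rings. Unlike
#' variance-style sharpness scores (e.g. the Tamura coefficient, available
#' as `metric = "tamura"`, whose focus is a minimum for phase-dominated
#' cells but a maximum for absorbing ones), the kurtosis criterion
#' localises the focus for absorbing cells, phase cells and mixtures
#' alike.
#'
#' @param h A [hologram()].
#' @param z_range Length-2 numeric, micrometres, `z_range[1] < z_range[2]`.
#' @param z_step Scan step in micrometres.
#' @param metric `"kurtosis"` (default) or `"tamura"` (negative Tamura
#'   coefficient, `-sd/mean`).
#' @param coarse_step Optional coarse first-pass step (micrometres): the
#'   range is first scanned at this step and only the neighbourhood of the
#'   coarse optimum is rescanned at `z_step`. `NULL` scans the whole range
#'   at `z_step`.
#' @return The focus distance `z0` in micrometres, with the scanned metric
#'   trace attached as attribute `"focus_trace"` (a tibble with `z` and
#'   `metric`).
#' @export
#' @examples
#' \donttest{
#' sc <- sample_scene(0, 5, phantom_params(frame_shape = c(256, 256)), seed = 3)
#' h <- simulate_hologram(sc, 457.5, noise = "none")
#' autofocus(h, c(800, 1200), 20)
#' }
autofocus <- function(h, z_range = c(500, 1500), z_step = 20,
                      metric = c("kurtosis", "tamura"), coarse_step = 3 * z_step) {
  stopifnot(is_hologram(h))
  metric <- match.arg(metric)
  if (length(z_range) != 2 || z_range[1] <= 0 || z_range[2] <= z_range[1]) {
    rlang::abort("`z_range` must be positive and ordered.", class = "holocyte_invalid_parameter")
  }
  check_positive_scalar(z_step, "z_step")
  score <- switch(metric,
    kurtosis = module_kurtosis,
    tamura = function(M) -tamura(M)
  )
  eval_at <- function(zz) {
    vapply(zz, function(z) score(Mod(backpropagate(h, z)$amplitude)), numeric(1))
  }
  if (!is.null(coarse_step) && coarse_step > z_step) {
    zc <- seq(z_range[1], z_range[2], by = coarse_step)
    mc <- eval_at(zc)
    z_peak <- zc[which.max(mc)]
    lo <- max(z_range[1], z_peak - coarse_step)
    hi <- min(z_range[2], z_peak + coarse_step)
    zf <- setdiff(seq(lo, hi, by = z_step), zc)
    mf <- eval_at(zf)
    zs <- c(zc, zf)
    metric <- c(mc, mf)
    # hill-climb: if the optimum sits at the edge of the fine window, the
    # true peak may lie just outside it -- extend one coarse step at a time
    repeat {
      fine <- zs >= lo & zs <= hi
      z_opt <- zs[fine][which.max(metric[fine])]
      if (z_opt <= lo + z_step / 2 && lo > z_range[1]) {
        new_lo <- max(z_range[1], lo - coarse_step)
        ze <- setdiff(seq(new_lo, lo - z_step, by = z_step), zs)
        if (length(ze)) {
          zs <- c(zs, ze)
          metric <- c(metric, eval_at(ze))
        }
        lo <- new_lo
      } else if (z_opt >= hi - z_step / 2 && hi < z_range[2]) {
        new_hi <- min(z_range[2], hi + coarse_step)
        ze <- setdiff(seq(hi + z_step, new_hi, by = z_step), zs)
        if (length(ze)) {
          zs <- c(zs, ze)
          metric <- c(metric, eval_at(ze))
        }
        hi <- new_hi
      } else {
        break
      }
    }
    o <- order(zs)
    zs <- zs[o]
    metric <- metric[o]
  } else {
    zs <- seq(z_range[1], z_range[2], by = z_step)
    metric <- eval_at(zs)
  }
  rng <- max(metric) - min(metric)
  if (!is.finite(rng) || rng < 0.05 * max(abs(metric), 1e-12)) {
    rlang::abort(
      "no focus found: sharpness metric is flat over the scanned range (featureless hologram?)",
      class = "holocyte_no_focus"
    )
  }
  i <- which.max(metric)
  z0 <- zs[i]
  if (i > 1 && i < length(zs) &&
    abs(zs[i] - zs[i - 1] - z_step) < 1e-9 && abs(zs[i + 1] - zs[i] - z_step) < 1e-9) {
    # parabolic refinement through the three points around the optimum
    y1 <- metric[i - 1]
    y2 <- metric[i]
    y3 <- metric[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps) {
      z0 <- zs[i] + z_step * 0.5 * (y1 - y3) / den
    }
  }
  attr(z0, "focus_trace") <- tibble::tibble(z = zs, metric = metric)
  z0
}

#' Fine focus refinement around a coarse estimate
#'
#' Rescans a narrow bracket about a coarse focus estimate and returns the
#' distance maximising the depth of the deepest (3x3-smoothed) module dip
#' below the background median. Within a bracket already known to contain
#' the focus this criterion tracks the exact plane where absorbing cells
#' are sharpest; it complements the global kurtosis scan of [autofocus()],
#' whose parabolic interpolation can sit a few micrometres off on crowded
#' frames -- enough to distort per-cell phase signatures.
#'
#' @param h A [hologram()].
#' @param z0 Coarse focus estimate, micrometres.
#' @param half_range Bracket half-width (default 20 um, one autofocus step).
#' @param step Scan step (default 5 um).
#' @param margin_px Frame margin ignored by the dip search.
#' @return Refined z0 in micrometres.
#' @export
refine_focus <- function(h, z0, half_range = 20, step = 5, margin_px = 12) {
  stopifnot(is_hologram(h))
  zs <- seq(z0 - half_range, z0 + half_range, by = step)
  zs <- zs[zs > 0]
  depth <- vapply(zs, function(z) {
    M <- smooth3(Mod(backpropagate(h, z)$amplitude))
    n <- nrow(M)
    m <- ncol(M)
    core <- M[(margin_px + 1):(n - margin_px), (margin_px + 1):(m - margin_px)]
    stats::median(M) - min(core)
  }, numeric(1))
  zs[which.max(depth)]
}

module_kurtosis <- function(M) {
  d <- as.vector(M) - stats::median(M)
  v <- mean(d^2)
  if (v < .Machine$double.eps) {
    return(3) # flat image: Gaussian-reference kurtosis
  }
  mean(d^4) / v^2
}

tamura <- function(M) {
  mu <- mean(M)
  if (mu <= 0) {
    return(0)
  }
  sqrt(stats::var(as.vector(M))) / mu
}

#' Iterative phase retrieval (twin-image suppression)
#'
#' Recovers the complex object-plane transmittance from one or more
#' phaseless intensity holograms by gradient descent on the amplitude
#' data-fidelity loss
#' \deqn{L(t) = \sum_c \| \,|P t| - \sqrt{I_c}\, \|^2,}
#' where \eqn{P} propagates the object-plane estimate to the sensor plane.
#' Each iteration takes a gradient step and projects onto the physical
#' object-domain constraint \eqn{|t| \le 1} (a passive sample cannot
#' amplify). The step is halved until the loss does not increase, so the
#' recorded `loss_trace` is non-increasing by construction. The iteration
#' is initialised from the plain back-propagation, so zero iterations
#' reproduce [backpropagate()] exactly.
#'
#' Multiple holograms of the same geometry (e.g. the three colour channels)
#' may be passed as a list; their losses are summed and a single object
#' estimate is returned. By default channels are reconstructed
#' independently (one call per channel), matching the downstream usage of
#' the blue channel for detection and the red channel for analysis.
#'
#' @param holograms A [hologram()] or a list of holograms sharing pitch and
#'   frame geometry.
#' @param z Object-plane distance in micrometres (estimate with
#'   [autofocus()] if unknown).
#' @param iterations Maximum number of accepted gradient steps (default 30).
#' @param step_size Initial gradient step (default 1).
#' @param reg_weight Optional Tikhonov weight pulling the estimate towards
#'   the unit background (default 0 = no regularisation).
#' @param max_halvings Step halvings attempted before declaring a plateau.
#' @return An object of class `holo_recon`: list with `field` (the
#'   object-plane [wave_field()]), `z0_global`, `loss_trace` (tibble
#'   `iteration`, `loss`), `iterations` (accepted steps), `converged`,
#'   `channel`.
#' @export
phase_retrieval <- function(holograms, z, iterations = 30, step_size = 1,
                            reg_weight = 0, max_halvings = 8) {
  hs <- if (is_hologram(holograms)) list(holograms) else holograms
  if (!length(hs) || !all(vapply(hs, is_hologram, logical(1)))) {
    rlang::abort("`holograms` must be a hologram or a list of holograms.")
  }
  pitch <- hs[[1]]$pitch
  dims <- dim(hs[[1]]$intensity)
  for (h in hs) {
    if (!identical(dim(h$intensity), dims) || h$pitch != pitch) {
      rlang::abort("all holograms must share pitch and frame geometry.",
        class = "holocyte_geometry_mismatch"
      )
    }
  }
  if (!is.numeric(z) || length(z) != 1 || z <= 0) {
    rlang::abort("`z` must be a positive distance in um.", class = "holocyte_invalid_parameter")
  }
  stopifnot(iterations >= 0)

  wl_um <- vapply(hs, function(h) h$wavelength * 1e-3, numeric(1))
  amps <- lapply(hs, function(h) {
    a <- sqrt(h$intensity)
    a / stats::median(a)
  })

  project <- function(t) {
    m <- Mod(t)
    over <- m > 1
    t[over] <- t[over] / m[over]
    t
  }
  # object plane -> sensor is a -z move in the sensor-at-origin frame
  forward <- function(t, k) propagate_matrix(t, pitch, wl_um[k], -z, pad = TRUE)
  backward <- function(r, k) propagate_matrix(r, pitch, wl_um[k], +z, pad = TRUE)
  # evaluate the loss and keep the sensor-plane fields: the accepted
  # candidate's forward fields are reused for the next gradient, halving
  # the number of transforms per iteration
  eval_loss <- function(t) {
    S <- lapply(seq_along(hs), function(k) forward(t, k))
    L <- 0
    for (k in seq_along(hs)) {
      L <- L + sum((Mod(S[[k]]) - amps[[k]])^2)
    }
    if (reg_weight > 0) L <- L + reg_weight * sum(Mod(t - 1)^2)
    list(loss = L, S = S)
  }

  # initialisation: back-propagated field of the first hologram
  t <- backward(amps[[1]] + 0i, 1)
  init_field <- t
  t <- project(t)
  cur <- eval_loss(t)
  L <- cur$loss
  trace <- L
  accepted <- 0L
  converged <- TRUE

  for (it in seq_len(iterations)) {
    g <- matrix(0 + 0i, dims[1], dims[2])
    for (k in seq_along(hs)) {
      S <- cur$S[[k]]
      resid <- (Mod(S) - amps[[k]]) * exp(1i * Arg(S))
      g <- g + backward(resid, k)
    }
    if (reg_weight > 0) g <- g + reg_weight * (t - 1)
    s <- step_size
    step_ok <- FALSE
    for (hh in seq_len(max_halvings)) {
      cand <- project(t - s * g)
      cand_eval <- eval_loss(cand)
      if (cand_eval$loss <= L) {
        t <- cand
        cur <- cand_eval
        L <- cand_eval$loss
        step_ok <- TRUE
        break
      }
      s <- s / 2
    }
    trace <- c(trace, L)
    if (!step_ok) {
      # plateau: no descent direction at the smallest step; a genuine loss
      # increase is impossible since candidates are only accepted on descent
      converged <- TRUE
      break
    }
    accepted <- accepted + 1L
  }

  if (iterations == 0) t <- init_field
  t <- remove_piston(t)
  structure(
    list(
      field = wave_field(t, pitch, hs[[1]]$wavelength, z_ref = z),
      z0_global = z,
      loss_trace = tibble::tibble(iteration = seq_along(trace) - 1L, loss = trace),
      iterations = accepted,
      converged = converged,
      channel = hs[[1]]$channel
    ),
    class = "holo_recon"
  )
}

#' @export
print.holo_recon <- function(x, ...) {
  lt <- x$loss_trace$loss
  cat(sprintf(
    "<holo_recon> %s channel, %d x %d px, z0 %.5g um, %d iterations, loss %.4g -> %.4g\n",
    x$channel, nrow(x$field$amplitude), ncol(x$field$amplitude),
    x$z0_global, x$iterations, lt[1], lt[length(lt)]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the loss trace of a reconstruction
#' @param x A `holo_recon` object.
#' @param ... Unused.
#' @return Tibble with `iteration` and `loss`.
#' @method tidy holo_recon
#' @export
tidy.holo_recon <- function(x, ...) x$loss_trace

#' One-row summary of a reconstruction
#' @param x A `holo_recon` object.
#' @param ... Unused.
#' @return One-row tibble: channel, z0, iterations, initial/final loss and
#'   the relative loss reduction.
#' @method glance holo_recon
#' @export
glance.holo_recon <- function(x, ...) {
  lt <- x$loss_trace$loss
  tibble::tibble(
    channel = x$channel,
    z0_global = x$z0_global,
    iterations = x$iterations,
    converged = x$converged,
    initial_loss = lt[1],
    final_loss = lt[length(lt)],
    loss_reduction = 1 - lt[length(lt)] / lt[1]
  )
}
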