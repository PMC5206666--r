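# Independent oracles and small builders shared across tests.

# Direct Rayleigh-Sommerfeld (first solution) summation: propagates a
# compact source distribution by evaluating the RS impulse response at
# every grid point, one source pixel at a time. Independent of the FFT
# angular-spectrum path. Valid as a quadrature only where the sampled
# kernel resolves its fringes (near-axis cone for smooth sources).
rs_direct_sum <- function(A, pitch, wl_um, z, tol = 1e-8) {
  n <- nrow(A)
  m <- ncol(A)
  k <- 2 * pi / wl_um
  sgn <- sign(z)
  za <- abs(z)
  xs <- (seq_len(n) - 1) * pitch
  ys <- (seq_len(m) - 1) * pitch
  out <- matrix(0 + 0i, n, m)
  idx <- which(Mod(A) > tol, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    sx <- xs[idx[s, 1]]
    sy <- ys[idx[s, 2]]
    DX <- outer(xs - sx, rep(1, m))
    DY <- outer(rep(1, n), ys - sy)
    r <- sqrt(DX^2 + DY^2 + za^2)
    # kernel for propagation by -d is the conjugate of the +d kernel
    h <- (za / (2 * pi)) * exp(1i * sgn * k * r) / r^2 * (1 / r - 1i * sgn * k) * pitch^2
    out <- out + A[idx[s, 1], idx[s, 2]] * h
  }
  out
}

# Hologram intensity of a compact object by the RS oracle: the uniform
# background propagates as the analytic plane wave exp(i k z); only the
# deviation (t - 1) needs the direct sum (linearity of propagation).
rs_hologram_intensity <- function(t_mat, pitch, wl_um, z) {
  dev <- t_mat - 1
  U <- exp(-1i * 2 * pi / wl_um * z) + rs_direct_sum(dev, pitch, wl_um, -z)
  Mod(U)^2
}

# greedy matching of detections to ground-truth cells
match_detections <- function(dets, cells, tol_px = 4) {
  used <- rep(FALSE, nrow(cells))
  tp <- 0L
  lab_ok <- 0L
  for (i in seq_len(nrow(dets))) {
    dd <- sqrt((cells$row_px - dets$row[i])^2 + (cells$col_px - dets$col[i])^2)
    j <- which.min(ifelse(used, Inf, dd))
    if (is.finite(dd[j]) && dd[j] <= tol_px) {
      tp <- tp + 1L
      used[j] <- TRUE
      if ("label" %in% names(dets) && cells$kind[j] == dets$label[i]) lab_ok <- lab_ok + 1L
    }
  }
  list(
    tp = tp,
    recall = tp / max(nrow(cells), 1L),
    precision = tp / max(nrow(dets), 1L),
    label_accuracy = lab_ok / max(tp, 1L)
  )
}

# a small scene with hand-placed cells (bypasses random placement)
manual_scene <- function(cells, frame_shape = c(128L, 128L), pitch = 1.67,
                         chamber_z = 1000, params = NULL) {
  if (is.null(params)) params <- phantom_params(frame_shape = frame_shape, pitch = pitch, chamber_z = chamber_z)
  if (!"z_um" %in% names(cells)) cells$z_um <- chamber_z
  structure(
    list(
      cells = tibble::as_tibble(cells), chamber_z = chamber_z,
      frame_shape = as.integer(frame_shape), pitch = pitch,
      seed = 0L, params = params
    ),
    class = "phantom_scene"
  )
}

one_cell_df <- function(kind = "erythrocyte", row = 64, col = 64, diam = 7,
                        phase = 0.9, absorption = 0.45) {
  tibble::tibble(
    kind = kind, row_px = row, col_px = col, diameter_um = diam,
    peak_phase = phase, absorption = absorption
  )
}

# brute-force ROC oracle: one confusion matrix per threshold
roc_bruteforce <- function(scores, truth) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  do.call(rbind, lapply(ths, function(t) {
    pred <- scores >= t
    data.frame(
      threshold = t,
      fpr = sum(pred & !truth) / sum(!truth),
      tpr = sum(pred & truth) / sum(truth)
    )
  }))
}
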