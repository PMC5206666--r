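#' Plot a module or phase image
#'
#' Raster plot of a reconstructed module (`|field|`) or phase
#' (`arg(field)`) image.
#'
#' @param field A [wave_field()] or `holo_recon`.
#' @param what `"module"` or `"phase"`.
#' @return A ggplot object.
#' @export
plot_field <- function(field, what = c("module", "phase")) {
  what <- match.arg(what)
  if (inherits(field, "holo_recon")) field <- field$field
  stopifnot(is_wave_field(field))
  A <- field$amplitude
  val <- if (what == "module") Mod(A) else Arg(A)
  # column-major vectorisation: row varies fastest
  df <- tibble::tibble(
    row = rep(seq_len(nrow(A)), times = ncol(A)),
    col = rep(seq_len(ncol(A)), each = nrow(A)),
    value = as.vector(val)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Loss trace of a phase-retrieval run
#' @param object A `holo_recon`.
#' @param ... Unused.
#' @return A ggplot of data-fidelity loss against iteration.
#' @method autoplot holo_recon
#' @export
autoplot.holo_recon <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "data-fidelity loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-cell Z-axis profiles
#'
#' Module and phase signatures of each cell against the propagation
#' distance from the sensor.
#'
#' @param profiles Long tibble from [compute_z_profiles()].
#' @param cells Optional subset of `cell_id`s to show.
#' @return A ggplot object, faceted module/phase.
#' @export
plot_z_profiles <- function(profiles, cells = NULL) {
  df <- profiles
  if (!is.null(cells)) df <- dplyr::filter(df, .data$cell_id %in% cells)
  df <- tidyr::pivot_longer(df, c("module", "phase"),
    names_to = "component", values_to = "value"
  )
  z0 <- attr(profiles, "z0")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$z_um, y = .data$value,
    group = .data$cell_id, colour = factor(.data$cell_id)
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Z (um from sensor)", y = NULL, colour = "cell") +
    ggplot2::theme_minimal()
  if (!is.null(z0)) p <- p + ggplot2::geom_vline(xintercept = z0, linetype = 3)
  p
}

#' Plot an ROC curve
#' @param roc Tibble from [roc_curve()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate") +
    ggplot2::theme_minimal()
}

#' Cohort scatter of leukocyte vs erythrocyte concentrations
#'
#' One point per specimen on log-scaled axes, with the two decision limits
#' drawn: the pleocytosis cutoff (horizontal) and the haemorrhage
#' erythrocyte limit (vertical).
#'
#' @param cohort Tibble with `leuko_conc`, `ery_conc` and optionally a
#'   `truth`/`call` column used for colour.
#' @param config A [gating_config()] (for the two limits).
#' @param colour Optional column (tidy-eval) mapped to point colour.
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, config = gating_config(), colour = NULL) {
  p <- ggplot2::ggplot(cohort, ggplot2::aes(
    x = .data$ery_conc + 1, y = .data$leuko_conc + 1,
    colour = {{ colour }}
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(
      yintercept = config$leukocyte_cutoff + 1,
      linetype = 2, colour = "red"
    ) +
    ggplot2::geom_vline(
      xintercept = config$erythrocyte_limit + 1,
      linetype = 2, colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "erythrocytes + 1 (cells/uL)",
      y = "leukocytes + 1 (cells/uL)"
    ) +
    ggplot2::theme_minimal()
  p
}
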