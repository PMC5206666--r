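#' ROC curve over a decision threshold
#'
#' Sweeps the rule "score >= threshold -> positive" over every distinct
#' score and returns one `(FPR, TPR)` point per threshold plus the two
#' infinite endpoints, so the curve always starts at `(0, 0)` and ends at
#' `(1, 1)`. Tied scores collapse to a single point.
#'
#' @param data Data frame with one row per specimen.
#' @param score Column (tidy-eval) holding the continuous statistic.
#' @param truth Column (tidy-eval) holding the binary truth; `TRUE`/1 (or
#'   the factor's second level) is the positive class.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered from `(0, 0)` to
#'   `(1, 1)`.
#' @export
#' @examples
#' df <- tibble::tibble(s = c(0.9, 0.8, 0.3, 0.2), y = c(TRUE, TRUE, FALSE, FALSE))
#' roc_curve(df, s, y)
roc_curve <- function(data, score, truth) {
  s <- dplyr::pull(data, {{ score }})
  y <- as_binary_truth(dplyr::pull(data, {{ truth }}))
  if (length(unique(y)) < 2) {
    rlang::abort("`truth` must contain both classes.", class = "holocyte_single_class")
  }
  n_pos <- sum(y)
  n_neg <- sum(!y)
  thresholds <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pts <- lapply(thresholds, function(t) {
    pred <- s >= t
    c(fpr = sum(pred & !y) / n_neg, tpr = sum(pred & y) / n_pos)
  })
  tibble::tibble(
    threshold = thresholds,
    fpr = vapply(pts, `[[`, numeric(1), "fpr"),
    tpr = vapply(pts, `[[`, numeric(1), "tpr")
  )
}

#' Area under an ROC curve (trapezoidal)
#' @param roc Tibble from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sensitivity and specificity of predicted calls
#'
#' @param data Data frame with one row per specimen.
#' @param predicted Column (tidy-eval) with the predicted binary call.
#' @param truth Column (tidy-eval) with the true binary label.
#' @return One-row tibble: `tp`, `fn`, `fp`, `tn`, `sensitivity`
#'   (`TP / (TP + FN)`), `specificity` (`TN / (TN + FP)`).
#' @export
sensitivity_specificity <- function(data, predicted, truth) {
  p <- as_binary_truth(dplyr::pull(data, {{ predicted }}))
  y <- as_binary_truth(dplyr::pull(data, {{ truth }}))
  tp <- sum(p & y)
  fn <- sum(!p & y)
  fp <- sum(p & !y)
  tn <- sum(!p & !y)
  tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

as_binary_truth <- function(x) {
  if (is.logical(x)) {
    return(x)
  }
  if (is.numeric(x)) {
    return(x != 0)
  }
  if (is.factor(x)) {
    return(x == levels(x)[2])
  }
  if (is.character(x)) {
    return(tolower(x) %in% c("positive", "true", "yes", "meningitis", "1"))
  }
  rlang::abort("cannot interpret truth/prediction column as binary.")
}

#' Inter-operator variability of manual counts
#'
#' Given a table of leukocyte counts (cells/uL) -- one row per specimen,
#' one column per operator -- classifies each operator's reading as
#' meningitis when the count reaches `cutoff`, forms the consensus class
#' (meningitis iff at least `quorum` operators call it), and reports how
#' many specimens were misclassified by at least one operator: overall,
#' among consensus-negative and among consensus-positive specimens. Rates
#' are percentages rounded half-up to one decimal. The statistics are
#' invariant to row and column order.
#'
#' @param counts Data frame of non-negative counts; an optional `specimen`
#'   column is carried through as an identifier, all other columns are
#'   operators.
#' @param cutoff Leukocytes/uL defining meningitis (default 10, `>=`).
#' @param quorum Operators required for consensus (default 3 of 5). A
#'   quorum that lets both classes reach consensus on the same specimen
#'   (possible when `quorum <= n_operators / 2`) raises an error for the
#'   affected specimen.
#' @return One-row tibble: `n_specimens`, `n_consensus_positive`,
#'   `n_consensus_negative`, `n_discordant`, `rate_overall_pct`,
#'   `n_discordant_negative`, `rate_negative_pct`, `n_discordant_positive`,
#'   `rate_positive_pct`; the per-specimen detail is attached as attribute
#'   `"per_specimen"`.
#' @export
interoperator_stats <- function(counts, cutoff = 10, quorum = 3) {
  counts <- tibble::as_tibble(counts)
  id <- if ("specimen" %in% names(counts)) counts$specimen else seq_len(nrow(counts))
  ops <- dplyr::select(counts, -dplyr::any_of("specimen"))
  if (!nrow(ops) || !ncol(ops)) {
    rlang::abort("`counts` needs at least one specimen and one operator column.")
  }
  if (quorum > ncol(ops)) {
    rlang::abort("`quorum` cannot exceed the number of operators.")
  }
  M <- as.matrix(ops)
  if (any(M < 0)) rlang::abort("counts must be non-negative.")
  cls <- M >= cutoff
  n_pos_votes <- rowSums(cls)
  n_ops <- ncol(cls)
  tie <- n_pos_votes >= quorum & (n_ops - n_pos_votes) >= quorum
  if (any(tie)) {
    rlang::abort(
      sprintf("consensus tie for specimen(s) %s with quorum %d of %d", paste(id[tie], collapse = ", "), quorum, n_ops),
      class = "holocyte_consensus_tie"
    )
  }
  consensus <- n_pos_votes >= quorum
  discordant <- ifelse(consensus, n_pos_votes < n_ops, n_pos_votes > 0)

  per <- tibble::tibble(
    specimen = id,
    consensus = ifelse(consensus, "meningitis", "non-meningitis"),
    n_positive_votes = n_pos_votes,
    discordant = discordant
  )
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else NA_real_
  out <- tibble::tibble(
    n_specimens = nrow(per),
    n_consensus_positive = sum(consensus),
    n_consensus_negative = sum(!consensus),
    n_discordant = sum(discordant),
    rate_overall_pct = pct(sum(discordant), nrow(per)),
    n_discordant_negative = sum(discordant & !consensus),
    rate_negative_pct = pct(sum(discordant & !consensus), sum(!consensus)),
    n_discordant_positive = sum(discordant & consensus),
    rate_positive_pct = pct(sum(discordant & consensus), sum(consensus))
  )
  attr(out, "per_specimen") <- per
  out
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Synthetic five-operator count table
#'
#' A deterministic 72-specimen, five-operator leukocyte count table whose
#' consensus structure matches the published inter-operator study summary:
#' 28 consensus-meningitis specimens of which 3 are misread by one
#' operator, and 44 consensus-negative specimens of which 9 are misread by
#' one operator. The individual count values are synthetic; only the
#' class structure is constrained. Also shipped as
#' `inst/extdata/operator_counts_synthetic.csv`.
#'
#' @param cutoff Classification cutoff used to build the table (10).
#' @return Tibble with `specimen` and operator columns `op1`..`op5`.
#' @export
synthetic_operator_counts <- function(cutoff = 10) {
  lo <- cutoff / 5 # clearly negative reading
  hi <- cutoff * 5 # clearly positive reading
  block <- function(n, base, deviant_value = NULL, deviant_op = 4L) {
    t(vapply(seq_len(n), function(i) {
      v <- rep(base, 5)
      if (!is.null(deviant_value)) v[deviant_op] <- deviant_value
      v
    }, numeric(5)))
  }
  M <- rbind(
    block(25, hi), # unanimous meningitis
    block(3, hi, deviant_value = lo), # one operator under-reads
    block(35, lo), # unanimous negative
    block(9, lo, deviant_value = hi) # one operator over-reads
  )
  colnames(M) <- paste0("op", 1:5)
  tibble::tibble(specimen = sprintf("S%02d", seq_len(nrow(M)))) |>
    dplyr::bind_cols(tibble::as_tibble(M))
}

#' Read an operator count table from CSV
#' @param path CSV with a `specimen` column and one column per operator.
#' @return Tibble suitable for [interoperator_stats()].
#' @export
read_operator_counts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
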