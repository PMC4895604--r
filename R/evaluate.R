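# Evaluation metrics: reproduction rate, negative predictive value,
# artefact-reduction percentage, and cross-condition fold comparisons.
# All percentages are rounded half-up to two decimals.

#' Reproduction rate (percentage)
#'
#' Fraction of validated positive sites the classifier accepts.
#' @param n_reproduced,n_validated_pos Counts,
#'   `0 <= n_reproduced <= n_validated_pos`, `n_validated_pos > 0`.
#' @return Percentage, 2-decimal half-up rounding.
#' @export
reproduction_rate <- function(n_reproduced, n_validated_pos) {
  stopifnot(n_validated_pos > 0, n_reproduced >= 0,
            n_reproduced <= n_validated_pos)
  round_half_up(100 * n_reproduced / n_validated_pos)
}

#' Negative predictive value (percentage)
#'
#' `100 * tn / (tn + fn)`: among rejected sites with validation status,
#' the fraction that are truly not editing events.
#' @param tn,fn True-negative and false-negative counts, `tn + fn > 0`.
#' @return Percentage, 2-decimal half-up rounding.
#' @export
npv <- function(tn, fn) {
  stopifnot(tn >= 0, fn >= 0, tn + fn > 0)
  round_half_up(100 * tn / (tn + fn))
}

#' Artefact-reduction percentage
#'
#' `100 * (1 - accepted / candidates)`.
#' @param candidates,accepted Counts, `0 <= accepted <= candidates`,
#'   `candidates > 0`.
#' @return Percentage, 2-decimal half-up rounding.
#' @export
reduction <- function(candidates, accepted) {
  stopifnot(candidates > 0, accepted >= 0, accepted <= candidates)
  round_half_up(100 * (1 - accepted / candidates))
}

#' Cross-condition fold comparison
#'
#' Elementwise max/min ratio of two equal-length positive count vectors
#' (e.g. reads, bases, raw RDDs, accepted RDDs of two conditions).
#'
#' @param rowA,rowB Named (or unnamed) positive count vectors.
#' @param names_A,names_B Row labels in the report.
#' @return A `ComparisonReport` data.table: one row per condition plus a
#'   `Fold` row (2-decimal half-up rounding).
#' @export
fold_compare <- function(rowA, rowB, names_A = "A", names_B = "B") {
  stopifnot(length(rowA) == length(rowB), all(rowA > 0), all(rowB > 0))
  fold <- round_half_up(pmax(rowA, rowB) / pmin(rowA, rowB))
  cn <- names(rowA) %||% paste0("V", seq_along(rowA))
  out <- data.table::as.data.table(rbind(rowA, rowB, fold))
  data.table::setnames(out, cn)
  out[, "condition" := c(names_A, names_B, "Fold")]
  data.table::setcolorder(out, "condition")
  out[]
}

#' Evaluate predictions against a validated site list
#'
#' Joins predictions to a validation list (`chrom`,`pos`,`label` with
#' labels `positive`/`negative`) by site and derives the confusion
#' counts and rates.  Validation sites absent from the prediction set
#' are reported (`n_unmatched`), never silently dropped.
#'
#' @param predictions Output of [rdd_predict()] (columns
#'   `chrom,pos,prob,accepted`).
#' @param validation Site table with a `label` column.
#' @param n_candidates Optional total raw-candidate count for the
#'   reduction percentage (default: number of predictions).
#' @return List of class `rdd_evaluation`: counts
#'   (`n_validated_pos`, `n_validated_neg`, `n_reproduced`, `tn`, `fn`,
#'   `n_unmatched`), and rates (`reproduction_rate`, `npv`, `reduction`)
#'   as percentages.
#' @export
evaluate_predictions <- function(predictions, validation,
                                 n_candidates = NULL) {
  pred <- data.table::as.data.table(predictions)
  val <- data.table::as.data.table(validation)
  check_site_cols(pred, c("chrom", "pos", "accepted"))
  check_site_cols(val, c("chrom", "pos", "label"))
  if (!nrow(val)) stop_rddkit("empty validation set")
  if (!all(val$label %in% c("positive", "negative")))
    stop_rddkit("validation labels must be 'positive' or 'negative'")
  val <- unique(val, by = c("chrom", "pos"))
  j <- pred[val, on = c("chrom", "pos")]
  unmatched <- is.na(j$accepted)
  jm <- j[!unmatched, ]
  n_vp <- sum(jm$label == "positive")
  n_vn <- sum(jm$label == "negative")
  n_rep <- sum(jm$label == "positive" & jm$accepted)
  tn <- sum(jm$label == "negative" & !jm$accepted)
  fn <- sum(jm$label == "positive" & !jm$accepted)
  if (is.null(n_candidates)) n_candidates <- nrow(pred)
  structure(list(
    n_validated_pos = n_vp, n_validated_neg = n_vn,
    n_reproduced = n_rep, tn = tn, fn = fn,
    n_unmatched = sum(unmatched),
    n_candidates = n_candidates, n_accepted = sum(pred$accepted),
    reproduction_rate = if (n_vp > 0) reproduction_rate(n_rep, n_vp) else NA_real_,
    npv = if (tn + fn > 0) npv(tn, fn) else NA_real_,
    reduction = if (n_candidates > 0) reduction(n_candidates, sum(pred$accepted)) else NA_real_),
    class = "rdd_evaluation")
}

#' @export
print.rdd_evaluation <- function(x, ...) {
  cat("RDD evaluation\n")
  cat(sprintf("  validated positive: %d (reproduced %d -> %.2f%%)\n",
              x$n_validated_pos, x$n_reproduced, x$reproduction_rate))
  cat(sprintf("  validated negative: %d (tn=%d, fn=%d -> NPV %.2f%%)\n",
              x$n_validated_neg, x$tn, x$fn, x$npv))
  cat(sprintf("  candidates %d, accepted %d -> reduction %.2f%%\n",
              x$n_candidates, x$n_accepted, x$reduction))
  if (x$n_unmatched)
    cat(sprintf("  %d validation site(s) absent from predictions\n", x$n_unmatched))
  invisible(x)
}
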