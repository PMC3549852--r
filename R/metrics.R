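# Performance assessment: confusion counts, Acc/Sn/Sp/MCC, stratified reports.

#' Confusion counts of a binary stability prediction
#'
#' The positive class is the stabilizing mutation (`"POSITIVE"`).
#'
#' @param truth,predicted Character vectors of `"POSITIVE"`/`"NEGATIVE"`
#'   labels, equal length.
#' @return One-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  if (length(truth) < 1) abort("need at least one prediction to count")
  stopifnot(all(truth %in% label_levels()), all(predicted %in% label_levels()))
  tibble(
    tp = sum(truth == "POSITIVE" & predicted == "POSITIVE"),
    fp = sum(truth == "NEGATIVE" & predicted == "POSITIVE"),
    fn = sum(truth == "POSITIVE" & predicted == "NEGATIVE"),
    tn = sum(truth == "NEGATIVE" & predicted == "NEGATIVE")
  )
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' Implements the standard formulas: `Acc = (TP+TN)/(TP+FP+TN+FN)`,
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)` and
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' MCC lies in `[-1, 1]`, with 0 a random prediction. When any marginal of the
#' MCC denominator is zero the coefficient is undefined; it is reported as 0
#' with `mcc_degenerate = TRUE`. Sn (Sp) is `NA` when there are no positives
#' (negatives).
#'
#' @param counts One-row tibble from [confusion_counts()], or `truth` and
#'   `predicted` vectors via the `...` shortcut of [stability_metrics()].
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `acc`, `sn`, `sp`, `mcc`,
#'   `mcc_degenerate`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  if (total == 0) abort("cannot compute metrics from zero counts")
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  degenerate <- denom == 0
  tibble(
    tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
    acc = (tp + tn) / total,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (degenerate) 0 else (tp * tn - fn * fp) / sqrt(denom),
    mcc_degenerate = degenerate
  )
}

#' @rdname metrics_from_counts
#' @param truth,predicted Label vectors (alternative entry point).
#' @export
stability_metrics <- function(truth, predicted) {
  metrics_from_counts(confusion_counts(truth, predicted))
}

#' Per-stratum performance report
#'
#' Computes metrics within each level of a stratifying annotation: secondary
#' structure class, RSA class, superfamily, or the pH x temperature condition
#' grid. Records lacking the annotation are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param records Curated tibble with `label` and the stratum column(s).
#' @param predicted Character vector of predicted labels, aligned to
#'   `records`.
#' @param by One of `"ss_class"`, `"rsa_class"`, `"superfamily"`,
#'   `"condition"` (the latter bins `ph` and `temperature` via
#'   [bin_condition()] and reports the 3x3 grid).
#' @return Tibble of one metrics row per non-empty stratum, with a `stratum`
#'   column (for `"condition"`, `ph_bin` and `temp_bin` columns).
#' @export
stratified_report <- function(records, predicted,
                              by = c("ss_class", "rsa_class", "superfamily",
                                     "condition")) {
  by <- arg_match(by)
  stopifnot(length(predicted) == nrow(records))
  df <- tibble(truth = records$label, predicted = predicted)
  if (by == "condition") {
    df <- dplyr::bind_cols(df, bin_condition(records$ph, records$temperature))
    keep <- !is.na(df$ph_bin) & !is.na(df$temp_bin)
    groups <- c("ph_bin", "temp_bin")
  } else {
    if (!by %in% names(records)) abort(paste0("records lack column ", by))
    df$stratum <- records[[by]]
    keep <- !is.na(df$stratum)
    groups <- "stratum"
  }
  if (!any(keep)) abort(paste0("no record carries the ", by, " annotation"))
  out <- df[keep, ] %>%
    group_by(dplyr::across(dplyr::all_of(groups))) %>%
    dplyr::reframe(metrics_from_counts(confusion_counts(truth, predicted)))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Accuracy grid over pH and temperature bins
#'
#' @inheritParams stratified_report
#' @return Tibble with `ph_bin` rows and one accuracy column per temperature
#'   bin (bins with no data are `NA`).
#' @export
condition_accuracy_grid <- function(records, predicted) {
  rep <- stratified_report(records, predicted, by = "condition")
  grid <- tidyr::complete(rep[, c("ph_bin", "temp_bin", "acc")],
                          ph_bin, temp_bin)
  tidyr::pivot_wider(grid, names_from = temp_bin, values_from = acc)
}
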