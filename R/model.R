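# The SVM meta-classifier: training, prediction, stratified k-fold
# cross-validation and the window-size sweep.

default_gamma <- 0.03125
default_cost <- 2

#' Train the stability meta-classifier
#'
#' Fits a C-classification SVM with an RBF kernel on an encoded feature
#' matrix. The kernel width and penalty default to the values tuned for this
#' integrator (`gamma = 0.03125`, `cost = 2`); features are 0/1 one-hot blocks
#' and are used unscaled.
#'
#' @param features A `stab_features` object from [encode_features()].
#' @param labels Character vector of `"POSITIVE"`/`"NEGATIVE"` truth labels.
#' @param gamma RBF kernel width.
#' @param cost Soft-margin penalty C.
#' @param seed Integer seed (the fit is deterministic given data order, but
#'   the seed is fixed for reproducibility of the underlying solver).
#' @return An object of class `istable_model`.
#' @export
train_classifier <- function(features, labels, gamma = default_gamma,
                             cost = default_cost, seed = 1) {
  stopifnot(inherits(features, "stab_features"))
  if (anyNA(features$x)) abort("feature matrix contains NA")
  if (length(labels) != nrow(features$x)) {
    abort("labels must match the feature matrix rows")
  }
  y <- factor(labels, levels = label_levels())
  if (anyNA(y)) abort("labels must be POSITIVE or NEGATIVE")
  if (dplyr::n_distinct(y) < 2) {
    abort("training set must contain both classes")
  }
  set.seed(seed)
  fit <- e1071::svm(x = features$x, y = y, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  structure(
    list(fit = fit, layout = features$layout, mode = features$mode,
         window_size = features$window_size,
         config = list(gamma = gamma, cost = cost, seed = seed),
         n_train = nrow(features$x),
         class_counts = table(y)),
    class = "istable_model"
  )
}

#' @export
print.istable_model <- function(x, ...) {
  cat("<istable_model> RBF SVM meta-classifier\n",
      "  mode: ", x$mode,
      if (!is.na(x$window_size)) paste0(" (window ", x$window_size, ")"),
      "\n  gamma = ", x$config$gamma, ", cost = ", x$config$cost,
      "\n  trained on ", x$n_train, " records (",
      x$class_counts[["POSITIVE"]], " stabilizing / ",
      x$class_counts[["NEGATIVE"]], " destabilizing)\n", sep = "")
  invisible(x)
}

#' Predict stability labels with a trained meta-classifier
#'
#' Refuses feature matrices whose layout (mode, window size, width) differs
#' from the training layout. The decision value is oriented so that positive
#' values favor the stabilizing class, and its sign always matches the
#' predicted label.
#'
#' @param object An `istable_model`.
#' @param features A `stab_features` object encoded under the same layout.
#' @param ... Unused.
#' @return Tibble with columns `.pred` (label) and `.decision` (signed SVM
#'   decision value).
#' @export
predict.istable_model <- function(object, features, ...) {
  stopifnot(inherits(features, "stab_features"))
  same <- identical(features$mode, object$mode) &&
    identical(features$window_size, object$window_size) &&
    ncol(features$x) == ncol(object$fit$SV)
  if (!same) {
    abort("feature layout does not match the model's training layout")
  }
  p <- predict(object$fit, features$x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # e1071 reports the decision value for the "first/second" class pair named
  # in the column; flip so positive always means POSITIVE.
  if (grepl("^NEGATIVE/", colnames(dv)[1])) dv <- -dv
  tibble(.pred = as.character(p), .decision = as.numeric(dv))
}

#' Label-stratified fold assignment
#'
#' Assigns each record to one of `k` folds, shuffling within each class so
#' both labels are spread evenly across folds. Deterministic given `seed`.
#'
#' @param labels Character label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k = 5, seed = 1) {
  stopifnot(k >= 2, length(labels) >= k)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate the meta-classifier
#'
#' 5-fold (by default) cross-validation with label-stratified random folds:
#' the dataset is split into k groups, each serving once as the test set while
#' the others train. TP/FP/FN/TN are pooled across folds before computing
#' metrics, so the report covers every record exactly once.
#'
#' @param records Curated tibble with `label` (and `window` for sequence
#'   modes).
#' @param predictions Prediction repository tibble.
#' @param mode Feature mode (see [feature_mode()]).
#' @param k Number of folds.
#' @param gamma,cost SVM hyperparameters.
#' @param seed Seed for the fold assignment.
#' @param folds Optional pre-computed fold vector (overrides `seed`), e.g. to
#'   reuse identical folds across a window-size sweep.
#' @return An object of class `stab_cv`: list with `metrics` (one-row tibble),
#'   `predictions` (per-record truth/prediction/decision/fold), `folds`, and
#'   the configuration.
#' @export
cross_validate <- function(records, predictions, mode = "seq_ws", k = 5,
                           gamma = default_gamma, cost = default_cost,
                           seed = 1, folds = NULL) {
  if (nrow(records) < k) abort("dataset smaller than the number of folds")
  if (dplyr::n_distinct(records$label) < 2) {
    abort("cross-validation needs both classes present")
  }
  features <- encode_features(records, predictions, mode = mode)
  if (is.null(folds)) folds <- make_folds(records$label, k = k, seed = seed)
  stopifnot(length(folds) == nrow(records))
  pred <- rep(NA_character_, nrow(records))
  dec <- rep(NA_real_, nrow(records))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (dplyr::n_distinct(records$label[tr]) < 2) {
      abort(paste0("fold ", f, " leaves a single-class training set; ",
                   "use a different seed or fewer folds"))
    }
    sub <- features
    sub$x <- features$x[tr, , drop = FALSE]
    model <- train_classifier(sub, records$label[tr], gamma = gamma,
                              cost = cost, seed = seed)
    te <- features
    te$x <- features$x[!tr, , drop = FALSE]
    out <- predict(model, te)
    pred[!tr] <- out$.pred
    dec[!tr] <- out$.decision
  }
  structure(
    list(
      metrics = stability_metrics(records$label, pred),
      predictions = tibble(key = mutation_key(records), fold = folds,
                           truth = records$label, .pred = pred,
                           .decision = dec),
      folds = folds,
      config = list(mode = mode, k = k, gamma = gamma, cost = cost,
                    seed = seed, n = nrow(records))
    ),
    class = "stab_cv"
  )
}

#' @export
print.stab_cv <- function(x, ...) {
  m <- x$metrics
  cat("<stab_cv> ", x$config$k, "-fold CV, mode ", x$config$mode, ", n = ",
      x$config$n, "\n", sep = "")
  cat(sprintf("  Sn %.3f  Sp %.3f  Acc %.3f  MCC %.3f\n",
              m$sn, m$sp, m$acc, m$mcc))
  invisible(x)
}

#' Cross-validate within one protein superfamily
#'
#' Restricts the dataset to a superfamily category (an independent, smaller
#' training set) and delegates to [cross_validate()].
#'
#' @inheritParams cross_validate
#' @param category One of `"enzyme"`, `"nucleic_acid_binding"`,
#'   `"ppi_related"` (or any level present in `records$superfamily`).
#' @return A `stab_cv` object for the restricted dataset.
#' @export
superfamily_cv <- function(records, predictions, category, mode = "seq_ws",
                           k = 5, gamma = default_gamma, cost = default_cost,
                           seed = 1) {
  sub <- records[!is.na(records$superfamily) & records$superfamily == category, ]
  if (nrow(sub) == 0) abort(paste0("no records in superfamily ", category))
  if (nrow(sub) < k) abort(paste0("superfamily ", category,
                                  " has fewer records than folds"))
  cross_validate(sub, predictions, mode = mode, k = k, gamma = gamma,
                 cost = cost, seed = seed)
}

#' Sweep the sequence-window size
#'
#' Re-extracts windows at each candidate size, then cross-validates with the
#' *same* fold assignment for every size so the comparison isolates the
#' window width.
#'
#' @param records Curated tibble (positions already sequence-relative).
#' @param sequences Named character vector of protein sequences.
#' @param predictions Prediction repository tibble.
#' @param sizes Odd window widths to try.
#' @param mode Feature mode (must use the sequence scheme).
#' @inheritParams cross_validate
#' @return An object of class `stab_sweep`: tibble with one row per size
#'   (`window_size`, `sn`, `sp`, `acc`, `mcc`), attributes `best_size`
#'   (argmax MCC), `folds`, and `fold_hash` (to verify identical folds).
#' @export
window_size_sweep <- function(records, sequences, predictions,
                              sizes = c(7, 9, 11, 13, 15, 17, 19),
                              mode = "seq_ws", k = 5, gamma = default_gamma,
                              cost = default_cost, seed = 1) {
  stopifnot(all(sizes %% 2 == 1))
  if (!feature_mode(mode)$use_sequence) {
    abort("window sweep requires a mode that uses the sequence scheme")
  }
  folds <- make_folds(records$label, k = k, seed = seed)
  rows <- purrr::map(sizes, function(w) {
    rec_w <- add_windows(records, sequences, window_size = w)
    cv <- cross_validate(rec_w, predictions, mode = mode, k = k, gamma = gamma,
                         cost = cost, seed = seed, folds = folds)
    dplyr::bind_cols(tibble(window_size = w),
                     cv$metrics[, c("sn", "sp", "acc", "mcc")])
  })
  out <- bind_rows(rows)
  attr(out, "best_size") <- out$window_size[which.max(out$mcc)]
  attr(out, "folds") <- folds
  attr(out, "fold_hash") <- paste(folds, collapse = ",")
  class(out) <- c("stab_sweep", class(out))
  out
}
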