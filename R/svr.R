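# Support vector regression of the ddG value itself.

#' Train the ddG regressor
#'
#' The structure-based regressor fits an epsilon-insensitive RBF SVR on the
#' ddG estimates of the four structure-based element predictors
#' (I-Mutant_PDB, AUTO-MUTE_RF, PoPMuSiC2.0, CUPSAT), optionally augmented
#' with the one-hot sequence scheme. In sequence-only input, just one element
#' predictor (I-Mutant_SEQ) emits a ddG value, so no regression is fitted:
#' the model simply passes that value through.
#'
#' @param records Curated tibble with observed `ddg` (and `window` if
#'   `include_sequence`).
#' @param predictions Prediction repository with `ddg_pred` values.
#' @param input `"structure"` (fit the SVR) or `"sequence"` (pass-through).
#' @param include_sequence Append the sequence-scheme one-hots to the ddG
#'   inputs (structure input only). Off by default: the regression integrates
#'   the element predictors' ddG estimates, and the high-dimensional one-hot
#'   block would dominate the RBF distance over the four informative inputs.
#' @param epsilon Insensitive-loss width.
#' @param gamma,cost RBF kernel width and penalty.
#' @param seed Integer seed.
#' @return An object of class `istable_ddg`.
#' @export
train_ddg_regressor <- function(records, predictions,
                                input = c("structure", "sequence"),
                                include_sequence = FALSE, epsilon = 0.1,
                                gamma = default_gamma, cost = default_cost,
                                seed = 1) {
  input <- arg_match(input)
  if (input == "sequence") {
    return(structure(list(input = "sequence"), class = "istable_ddg"))
  }
  x <- ddg_feature_matrix(records, predictions, include_sequence)
  y <- records$ddg
  if (dplyr::n_distinct(y) < 2) {
    abort("observed ddG values are constant; nothing to regress")
  }
  set.seed(seed)
  fit <- e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = cost, epsilon = epsilon,
                    scale = FALSE)
  structure(
    list(input = "structure", fit = fit, include_sequence = include_sequence,
         n_features = ncol(x),
         config = list(epsilon = epsilon, gamma = gamma, cost = cost,
                       seed = seed)),
    class = "istable_ddg"
  )
}

#' Predict ddG values
#'
#' @param object An `istable_ddg` model.
#' @param records Curated tibble of query mutations.
#' @param predictions Prediction repository for the queries.
#' @param ... Unused.
#' @return Numeric vector of predicted ddG (kcal/mol). The sequence-only
#'   model returns the I-Mutant_SEQ ddG estimate verbatim (`NA` when that
#'   predictor gave no answer).
#' @export
predict.istable_ddg <- function(object, records, predictions, ...) {
  if (object$input == "sequence") {
    pr <- predictions[predictions$predictor == "I-Mutant_SEQ", ]
    idx <- match(mutation_key(records), mutation_key(pr))
    return(ifelse(is.na(idx), NA_real_, pr$ddg_pred[idx]))
  }
  x <- ddg_feature_matrix(records, predictions, object$include_sequence)
  if (ncol(x) != object$n_features) {
    abort("ddG feature layout does not match the trained regressor")
  }
  as.numeric(predict(object$fit, x))
}

# records x inputs matrix: one column of predicted ddG per structure-based
# predictor (missing answers as 0) plus, optionally, the sequence scheme.
ddg_feature_matrix <- function(records, predictions, include_sequence) {
  key <- mutation_key(records)
  cols <- lapply(svr_input_predictors(), function(p) {
    pr <- predictions[predictions$predictor == p, ]
    idx <- match(key, mutation_key(pr))
    v <- ifelse(is.na(idx), NA_real_, pr$ddg_pred[idx])
    ifelse(is.na(v), 0, v)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- svr_input_predictors()
  if (include_sequence) {
    seq <- encode_features(records, predictions = NULL, mode = "istable_seq")
    # drop the two predictor blocks (all NULL_PRED here); keep sequence part
    keep <- seq$layout$kind %in% c("window", "mutant")
    width <- sum(seq$layout$length[keep])
    x <- cbind(x, seq$x[, seq_len(width), drop = FALSE])
  }
  x
}

#' Held-out evaluation of the ddG regressor
#'
#' k-fold cross-validation pooling the held-out predictions, reporting the
#' Pearson correlation between observed and predicted ddG and the RMSE of the
#' residuals, plus the same two statistics on the training fit.
#'
#' @inheritParams train_ddg_regressor
#' @param k Number of folds.
#' @return Tibble with rows `cv` and `training`: columns `r` (Pearson) and
#'   `rmse` (kcal/mol), plus `n`.
#' @export
ddg_regression_cv <- function(records, predictions, include_sequence = FALSE,
                              epsilon = 0.1, gamma = default_gamma,
                              cost = default_cost, k = 5, seed = 1) {
  folds <- make_folds(records$label, k = k, seed = seed)
  pred <- rep(NA_real_, nrow(records))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- train_ddg_regressor(records[tr, ], predictions,
                             include_sequence = include_sequence,
                             epsilon = epsilon, gamma = gamma, cost = cost,
                             seed = seed)
    pred[!tr] <- predict(m, records[!tr, ], predictions)
  }
  full <- train_ddg_regressor(records, predictions,
                              include_sequence = include_sequence,
                              epsilon = epsilon, gamma = gamma, cost = cost,
                              seed = seed)
  fit_pred <- predict(full, records, predictions)
  obs <- records$ddg
  tibble(
    set = c("cv", "training"),
    r = c(cor(obs, pred), cor(obs, fit_pred)),
    rmse = c(sqrt(mean((obs - pred)^2)), sqrt(mean((obs - fit_pred)^2))),
    n = nrow(records)
  )
}
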