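# Element-predictor layer: uniform backend interface, prediction repository
# persistence, call harmonization, and the majority-voting baseline.

#' Validate a prediction repository
#'
#' A repository is a tibble with one row per (mutation, predictor) pair:
#' columns `pdb_id`, `chain`, `position`, `wild_aa`, `mutant_aa`, `predictor`,
#' `call` and optionally `ddg_pred`. A lookup for an absent pair yields a null
#' prediction, so a repository never needs to be complete.
#'
#' @param predictions Tibble to validate.
#' @return The validated tibble (invisibly usable in a pipe).
#' @export
prediction_repository <- function(predictions) {
  need <- c("pdb_id", "position", "wild_aa", "mutant_aa", "predictor", "call")
  absent <- setdiff(need, names(predictions))
  if (length(absent) > 0) {
    abort(paste0("prediction table lacks column(s): ",
                 paste(absent, collapse = ", ")))
  }
  if (!"chain" %in% names(predictions)) predictions$chain <- NA_character_
  if (!"ddg_pred" %in% names(predictions)) predictions$ddg_pred <- NA_real_
  bad_p <- setdiff(unique(predictions$predictor), element_predictors())
  if (length(bad_p) > 0) {
    abort(paste0("unknown predictor id: ", bad_p[1]))
  }
  bad_c <- setdiff(unique(predictions$call), call_levels())
  if (length(bad_c) > 0) {
    abort(paste0("malformed call token: ", bad_c[1]))
  }
  k <- paste(mutation_key(predictions), predictions$predictor)
  if (anyDuplicated(k)) {
    abort(paste0("duplicate repository entry: ", k[which(duplicated(k))[1]]))
  }
  # stored ddG must agree in sign with the stored call (stabilizing-positive)
  has <- !is.na(predictions$ddg_pred) & predictions$ddg_pred != 0
  incons <- has & ((predictions$ddg_pred > 0) != (predictions$call == "INCREASE"))
  if (any(incons)) {
    abort("ddg_pred sign inconsistent with call in repository")
  }
  as_tibble(predictions)
}

#' Read / write a prediction repository as TSV
#'
#' The TSV round-trips bit-exactly: `read_predictions(write_predictions(x, p))`
#' equals `x`.
#'
#' @param predictions Repository tibble.
#' @param path TSV file path.
#' @return `read_predictions` returns the validated repository;
#'   `write_predictions` returns `path` invisibly.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(paste0("prediction file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    pdb_id = "c", chain = "c", position = "i", wild_aa = "c", mutant_aa = "c",
    predictor = "c", call = "c", ddg_pred = "d"), progress = FALSE)
  prediction_repository(df)
}

#' @rdname read_predictions
#' @export
write_predictions <- function(predictions, path) {
  prediction_repository(predictions)
  readr::write_tsv(
    predictions[, c("pdb_id", "chain", "position", "wild_aa", "mutant_aa",
                    "predictor", "call", "ddg_pred")],
    path, progress = FALSE)
  invisible(path)
}

#' Query element predictors through a backend
#'
#' Backends replace the original web servers behind one interface: a backend
#' is a function `(records, predictor_id) -> tibble(call, ddg_pred)` with one
#' row per record. Two backends ship: [cache_backend()] serves archived
#' predictions from a repository (misses become null predictions) and
#' [simulator_backend()] draws synthetic calls from predictor profiles.
#'
#' @param records Mutation tibble.
#' @param backend Backend function.
#' @param predictors Predictor ids to query (default all seven).
#' @return A prediction repository tibble covering
#'   `records x predictors`.
#' @export
query_predictions <- function(records, backend,
                              predictors = element_predictors()) {
  if (!is.function(backend)) abort("no backend registered")
  out <- purrr::map(predictors, function(p) {
    ans <- backend(records, p)
    tibble(
      pdb_id = records$pdb_id, chain = records$chain,
      position = records$position, wild_aa = records$wild_aa,
      mutant_aa = records$mutant_aa, predictor = p,
      call = ans$call, ddg_pred = ans$ddg_pred %||% NA_real_
    )
  })
  prediction_repository(bind_rows(out))
}

#' @rdname query_predictions
#' @param predictions Archived repository tibble backing the cache.
#' @export
cache_backend <- function(predictions) {
  predictions <- prediction_repository(predictions)
  function(records, predictor_id) {
    pr <- predictions[predictions$predictor == predictor_id, ]
    idx <- match(mutation_key(records), mutation_key(pr))
    tibble(
      call = ifelse(is.na(idx), "NULL_PRED", pr$call[idx]),
      ddg_pred = ifelse(is.na(idx), NA_real_, pr$ddg_pred[idx])
    )
  }
}

#' @rdname query_predictions
#' @param profiles Predictor profile tibble (see [predictor_profiles()]).
#' @param seed Integer seed; identical seeds give identical predictions.
#' @export
simulator_backend <- function(profiles, seed = 1) {
  function(records, predictor_id) {
    repo <- simulate_predictions(records, profiles[profiles$predictor == predictor_id, ],
                                 seed = seed + match(predictor_id, element_predictors()))
    repo[, c("call", "ddg_pred")]
  }
}

#' Convert a predicted ddG into a 3-state call
#'
#' After harmonizing to the stabilizing-positive convention, positive values
#' become `INCREASE`, negative `DECREASE`, and exactly zero `NULL_PRED`
#' (no directional information).
#'
#' @param ddg_pred Numeric vector of predicted ddG values.
#' @param convention Sign convention of the emitting predictor.
#' @return Character vector of calls.
#' @export
ddg_to_call <- function(ddg_pred, convention = c("istable", "popmusic")) {
  convention <- arg_match(convention)
  if (convention == "popmusic") ddg_pred <- -ddg_pred
  dplyr::case_when(ddg_pred > 0 ~ "INCREASE", ddg_pred < 0 ~ "DECREASE",
                   .default = "NULL_PRED")
}

#' Majority vote over element-predictor calls
#'
#' Null predictions are excluded; the class with more votes wins. A tie
#' (including the all-null case) defaults to `NEGATIVE` — destabilizing is the
#' majority class in every curated stability dataset — and is flagged so
#' degenerate votes stay auditable.
#'
#' @param calls Character vector of calls for one mutation.
#' @return The label, with attribute `tie` (logical).
#' @export
majority_vote <- function(calls) {
  stopifnot(all(calls %in% call_levels()))
  inc <- sum(calls == "INCREASE")
  dec <- sum(calls == "DECREASE")
  label <- if (inc > dec) "POSITIVE" else "NEGATIVE"
  attr(label, "tie") <- inc == dec
  label
}

#' Majority-vote labels for every mutation in a repository
#'
#' @param predictions Prediction repository tibble.
#' @return Tibble with the mutation key columns plus `vote`
#'   (`POSITIVE`/`NEGATIVE`) and `tie` (logical).
#' @export
majority_vote_table <- function(predictions) {
  predictions <- prediction_repository(predictions)
  predictions %>%
    group_by(pdb_id, chain, position, wild_aa, mutant_aa) %>%
    summarise(
      vote = as.character(majority_vote(call)),
      tie = attr(majority_vote(call), "tie"),
      .groups = "drop"
    )
}
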