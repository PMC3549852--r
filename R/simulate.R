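# Synthetic fixtures: mutation datasets and element-predictor outputs with the
# statistical structure of curated stability data, so the whole pipeline runs
# without any external service.

#' Default strata weights of the simulator
#'
#' Mixing proportions for the annotation strata of simulated records. The
#' defaults reflect the make-up of curated mutation sets: mostly near-neutral
#' pH and sub-40-degree experiments, helix/sheet/coil in roughly equal parts,
#' buried sites overrepresented, enzymes the largest superfamily.
#'
#' @return Named list of named probability vectors (`ph`, `temperature`,
#'   `ss`, `rsa`, `superfamily`).
#' @export
default_strata_weights <- function() {
  list(
    ph = c("<=6" = 0.35, "6-8" = 0.5, ">8" = 0.15),
    temperature = c("<=37" = 0.6, "37-65" = 0.3, ">65" = 0.1),
    ss = c(helix = 0.35, sheet = 0.3, other = 0.35),
    rsa = c(B = 0.45, P = 0.3, E = 0.25),
    superfamily = c(enzyme = 0.45, nucleic_acid_binding = 0.15,
                    ppi_related = 0.2, other = 0.2)
  )
}

#' Simulate a raw mutation dataset
#'
#' Generates synthetic proteins (uniform-random sequences over the 20 amino
#' acids) and single-point mutations on them. Class labels are drawn with the
#' configured stabilizing fraction — curated stability sets run roughly 2:1
#' destabilizing:stabilizing, hence the default of 1/3 — and ddG magnitudes
#' are exponential with mean `ddg_scale`, signed by the label, so only the
#' sign carries label information. Mutation keys are unique by construction
#' (no planted duplicates). Deterministic per seed.
#'
#' @param n Number of mutation records (>= 10).
#' @param positive_fraction Probability a record is stabilizing (in (0,1),
#'   bounds excluded; exactly 0/1 are allowed for degenerate test fixtures).
#' @param ddg_scale Mean |ddG| in kcal/mol.
#' @param n_proteins Number of synthetic proteins (default `ceiling(n / 25)`,
#'   at least 5).
#' @param seq_length Range of protein lengths.
#' @param strata_weights See [default_strata_weights()].
#' @param seed Integer seed.
#' @return List with `records` (raw mutation tibble, compile-ready) and
#'   `sequences` (named character vector, one per synthetic protein).
#' @export
simulate_dataset <- function(n, positive_fraction = 1/3, ddg_scale = 1,
                             n_proteins = NULL,
                             seq_length = c(60, 200),
                             strata_weights = default_strata_weights(),
                             seed = 1) {
  stopifnot(n >= 10, positive_fraction >= 0, positive_fraction <= 1)
  set.seed(seed)
  if (is.null(n_proteins)) n_proteins <- max(5L, ceiling(n / 25))
  pdb_ids <- sprintf("SY%02X", seq_len(n_proteins) - 1L)
  lens <- sample(seq(seq_length[1], seq_length[2]), n_proteins, replace = TRUE)
  sequences <- setNames(vapply(lens, function(L) {
    paste(sample(standard_aa(), L, replace = TRUE), collapse = "")
  }, character(1)), pdb_ids)

  # unique (protein, position) pairs guarantee unique mutation keys
  pool <- tibble(
    pdb_id = rep(pdb_ids, times = lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE)
  )
  if (n > nrow(pool)) abort("too many records for the simulated proteins")
  picked <- pool[sample.int(nrow(pool), n), ]

  wild <- unname(substr(sequences[picked$pdb_id], picked$position,
                        picked$position))
  mutant <- vapply(wild, function(w) sample(setdiff(standard_aa(), w), 1),
                   character(1), USE.NAMES = FALSE)
  label <- ifelse(runif(n) < positive_fraction, "POSITIVE", "NEGATIVE")
  ddg <- ifelse(label == "POSITIVE", 1, -1) * rexp(n, rate = 1 / ddg_scale)

  sw <- strata_weights
  ph_bin <- sample(names(sw$ph), n, replace = TRUE, prob = sw$ph)
  ph <- dplyr::case_when(
    ph_bin == "<=6" ~ runif(n, 2, 6),
    ph_bin == "6-8" ~ runif(n, 6, 8) + 1e-9,
    .default = runif(n, 8, 11) + 1e-9
  )
  temp_bin <- sample(names(sw$temperature), n, replace = TRUE,
                     prob = sw$temperature)
  temperature <- dplyr::case_when(
    temp_bin == "<=37" ~ runif(n, 4, 37),
    temp_bin == "37-65" ~ runif(n, 37, 65) + 1e-9,
    .default = runif(n, 65, 95) + 1e-9
  )
  ss_class <- sample(names(sw$ss), n, replace = TRUE, prob = sw$ss)
  ss <- c(helix = "H", sheet = "E", other = "C")[ss_class]
  rsa_bin <- sample(names(sw$rsa), n, replace = TRUE, prob = sw$rsa)
  rsa <- dplyr::case_when(
    rsa_bin == "B" ~ runif(n, 0, 20 - 1e-9),
    rsa_bin == "P" ~ runif(n, 20, 50 - 1e-9),
    .default = runif(n, 50, 100)
  )
  superfamily <- sample(names(sw$superfamily), n, replace = TRUE,
                        prob = sw$superfamily)

  records <- tibble(
    pdb_id = picked$pdb_id, chain = "A", position = picked$position,
    wild_aa = wild, mutant_aa = mutant, ph = ph, temperature = temperature,
    ddg = ddg, source = "simulated", ss = unname(ss), rsa = rsa,
    superfamily = superfamily
  )
  list(records = records, sequences = sequences)
}

#' Simulate element-predictor outputs
#'
#' Draws one 3-state call per (record, predictor) pair, conditionally
#' independent given the truth: a null prediction with probability
#' `null_rate`, otherwise the correct direction with probability `sensitivity`
#' (stabilizing records) or `specificity` (destabilizing records), otherwise
#' the wrong direction. Predictors flagged `emits_ddg` also report a ddG
#' estimate whose sign matches the call and whose magnitude is the true |ddG|
#' plus Gaussian noise.
#'
#' @param records Mutation tibble with `ddg` (truth labels derived from its
#'   sign).
#' @param profiles Tibble with columns `predictor`, `sensitivity`,
#'   `specificity`, `null_rate` and optionally `emits_ddg` (see
#'   [predictor_profiles()]).
#' @param seed Integer seed.
#' @param ddg_noise SD (kcal/mol) of the noise on emitted |ddG|.
#' @return Prediction repository tibble.
#' @export
simulate_predictions <- function(records, profiles, seed = 1, ddg_noise = 0.8) {
  need <- c("predictor", "sensitivity", "specificity", "null_rate")
  if (!all(need %in% names(profiles))) {
    abort("profiles must have predictor, sensitivity, specificity, null_rate")
  }
  if (!"emits_ddg" %in% names(profiles)) {
    profiles$emits_ddg <- profiles$predictor %in% ddg_emitting_predictors()
  }
  stopifnot(all(profiles$sensitivity >= 0 & profiles$sensitivity <= 1),
            all(profiles$specificity >= 0 & profiles$specificity <= 1),
            all(profiles$null_rate >= 0 & profiles$null_rate <= 1))
  set.seed(seed)
  n <- nrow(records)
  positive <- records$ddg > 0
  out <- purrr::map(seq_len(nrow(profiles)), function(i) {
    pf <- profiles[i, ]
    u_null <- runif(n)
    u_call <- runif(n)
    correct <- ifelse(positive, u_call < pf$sensitivity,
                      u_call < pf$specificity)
    call <- ifelse(u_null < pf$null_rate, "NULL_PRED",
                   ifelse(positive == correct, "INCREASE", "DECREASE"))
    ddg_pred <- NA_real_
    if (pf$emits_ddg) {
      mag <- pmax(abs(abs(records$ddg) + rnorm(n, 0, ddg_noise)), 1e-6)
      ddg_pred <- ifelse(call == "NULL_PRED", NA_real_,
                         ifelse(call == "INCREASE", mag, -mag))
    }
    tibble(
      pdb_id = records$pdb_id, chain = records$chain,
      position = records$position, wild_aa = records$wild_aa,
      mutant_aa = records$mutant_aa, predictor = pf$predictor,
      call = call, ddg_pred = ddg_pred
    )
  })
  prediction_repository(bind_rows(out))
}

#' Empirical sensitivity/specificity profiles of the element predictors
#'
#' Returns the published per-predictor (Sn, Sp) operating points on one of the
#' three curated benchmark datasets (M1311, M1820, or the merged M3131), for
#' use as simulator profiles. The null rate is not published per predictor; a
#' small default models the occasional unanswered query.
#'
#' @param dataset `"M3131"` (default), `"M1311"` or `"M1820"`.
#' @param null_rate Null-prediction probability applied to every predictor.
#' @return Profile tibble for [simulate_predictions()].
#' @export
predictor_profiles <- function(dataset = c("M3131", "M1311", "M1820"),
                               null_rate = 0.02) {
  dataset <- arg_match(dataset)
  sn_sp <- switch(dataset,
    M1311 = list(
      "I-Mutant_PDB" = c(0.555, 0.922), "I-Mutant_SEQ" = c(0.702, 0.973),
      "AUTO-MUTE_RF" = c(0.893, 0.991), "AUTO-MUTE_SVM" = c(0.772, 0.975),
      "MUPRO_SVM" = c(0.775, 0.956), "PoPMuSiC2.0" = c(0.313, 0.941),
      "CUPSAT" = c(0.579, 0.823)),
    M1820 = list(
      "I-Mutant_PDB" = c(0.198, 0.906), "I-Mutant_SEQ" = c(0.212, 0.899),
      "AUTO-MUTE_RF" = c(0.129, 0.985), "AUTO-MUTE_SVM" = c(0.067, 0.965),
      "MUPRO_SVM" = c(0.276, 0.885), "PoPMuSiC2.0" = c(0.303, 0.952),
      "CUPSAT" = c(0.370, 0.757)),
    M3131 = list(
      "I-Mutant_PDB" = c(0.377, 0.916), "I-Mutant_SEQ" = c(0.457, 0.934),
      "AUTO-MUTE_RF" = c(0.511, 0.989), "AUTO-MUTE_SVM" = c(0.420, 0.969),
      "MUPRO_SVM" = c(0.526, 0.908), "PoPMuSiC2.0" = c(0.308, 0.945),
      "CUPSAT" = c(0.474, 0.780))
  )
  tibble(
    predictor = element_predictors(),
    sensitivity = unname(vapply(sn_sp[element_predictors()], `[`, numeric(1), 1)),
    specificity = unname(vapply(sn_sp[element_predictors()], `[`, numeric(1), 2)),
    null_rate = null_rate,
    emits_ddg = element_predictors() %in% ddg_emitting_predictors()
  )
}
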