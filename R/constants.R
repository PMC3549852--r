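# Fixed vocabularies shared across the package.

#' The 21-symbol residue alphabet used by the sequence scheme
#'
#' The 20 standard amino-acid one-letter codes in alphabetical order, followed
#' by `"-"`, the pad symbol for window positions that fall beyond a sequence
#' terminus. The position of each symbol in this vector is its one-hot index,
#' so the ordering is part of the feature layout and must never change.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' The seven element predictors, in canonical block order
#'
#' Order matters: the website-result scheme concatenates one 3-bit block per
#' predictor in exactly this order, and trained models embed it in their
#' feature layout.
#'
#' @return Character vector of length 7.
#' @export
element_predictors <- function() {
  c("I-Mutant_PDB", "I-Mutant_SEQ", "AUTO-MUTE_RF", "AUTO-MUTE_SVM",
    "MUPRO_SVM", "PoPMuSiC2.0", "CUPSAT")
}

# Predictors whose simulated output includes a ddG estimate. The four
# structure-based ones feed the SVR; I-Mutant_SEQ additionally emits ddG so the
# sequence-only regressor has a value to pass through.
ddg_emitting_predictors <- function() {
  c("I-Mutant_PDB", "I-Mutant_SEQ", "AUTO-MUTE_RF", "PoPMuSiC2.0", "CUPSAT")
}

# Inputs of the structure-based ddG regressor.
svr_input_predictors <- function() {
  c("I-Mutant_PDB", "AUTO-MUTE_RF", "PoPMuSiC2.0", "CUPSAT")
}

call_levels <- function() c("DECREASE", "NULL_PRED", "INCREASE")
label_levels <- function() c("NEGATIVE", "POSITIVE")

#' Feature modes of the meta-classifier
#'
#' Each mode names which feature blocks enter the SVM:
#' \describe{
#'   \item{`seq_ws`}{sequence scheme + all seven predictor blocks (the default
#'     integrator).}
#'   \item{`ws_only`}{the seven predictor blocks alone, no sequence.}
#'   \item{`seq_ws_no_amrf`}{sequence scheme + six predictors, dropping
#'     AUTO-MUTE_RF.}
#'   \item{`istable_seq`}{sequence scheme + the two sequence-input predictors
#'     only (I-Mutant_SEQ, MUPRO_SVM) — the sequence-only integrator.}
#' }
#'
#' @param mode Mode name.
#' @return A list with elements `use_sequence` (logical) and `predictors`
#'   (character vector, subset of [element_predictors()] in canonical order).
#' @export
feature_mode <- function(mode = c("seq_ws", "ws_only", "seq_ws_no_amrf",
                                  "istable_seq")) {
  mode <- arg_match(mode)
  all <- element_predictors()
  switch(mode,
    seq_ws         = list(mode = mode, use_sequence = TRUE,  predictors = all),
    ws_only        = list(mode = mode, use_sequence = FALSE, predictors = all),
    seq_ws_no_amrf = list(mode = mode, use_sequence = TRUE,
                          predictors = setdiff(all, "AUTO-MUTE_RF")),
    istable_seq    = list(mode = mode, use_sequence = TRUE,
                          predictors = c("I-Mutant_SEQ", "MUPRO_SVM"))
  )
}

# Internal key helpers -------------------------------------------------------

# Canonical mutation key columns (chain included when known).
key_cols <- function() c("pdb_id", "chain", "position", "wild_aa", "mutant_aa")

mutation_key <- function(df) {
  chain <- if ("chain" %in% names(df)) df$chain else NA_character_
  chain <- ifelse(is.na(chain), "", chain)
  paste(df$pdb_id, chain, df$position, df$wild_aa, df$mutant_aa, sep = "|")
}

# Key that ignores the chain entirely (used where chain may be absent on one
# side of a comparison).
mutation_key_nochain <- function(df) {
  paste(df$pdb_id, df$position, df$wild_aa, df$mutant_aa, sep = "|")
}

standard_aa <- function() setdiff(aa_alphabet(), "-")
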