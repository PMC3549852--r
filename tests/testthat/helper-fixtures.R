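# Shared fixture builders. Everything is generated in code; no binary files.

# A minimal raw mutation tibble with explicit fields.
make_records <- function(pdb_id, position, wild_aa, mutant_aa, ddg,
                         chain = "A", ph = 7, temperature = 25) {
  tibble::tibble(
    pdb_id = pdb_id, chain = chain, position = position, wild_aa = wild_aa,
    mutant_aa = mutant_aa, ph = ph, temperature = temperature, ddg = ddg,
    source = "fixture"
  )
}

# An empty but schema-valid prediction repository.
empty_repo <- function() {
  tibble::tibble(
    pdb_id = character(), chain = character(), position = integer(),
    wild_aa = character(), mutant_aa = character(), predictor = character(),
    call = character(), ddg_pred = double()
  )
}

# A fully-null repository covering records x predictors (sequence-only signal).
null_repo <- function(records) {
  dplyr::bind_rows(lapply(element_predictors(), function(p) {
    tibble::tibble(
      pdb_id = records$pdb_id, chain = records$chain,
      position = records$position, wild_aa = records$wild_aa,
      mutant_aa = records$mutant_aa, predictor = p, call = "NULL_PRED",
      ddg_pred = NA_real_
    )
  }))
}

# Write a mutation table TSV from a data frame of character columns.
write_table_fixture <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# A compiled synthetic dataset + matching predictions, memoised per test run
# so several tests can share one moderately sized simulation.
shared_sim <- local({
  cache <- NULL
  function(n = 400, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache) || cache$key != key) {
      sim <- simulate_dataset(n = n, seed = seed)
      cur <- compile_mutations(sim$records, sim$sequences, window_size = 11)
      preds <- simulate_predictions(cur, predictor_profiles("M3131"),
                                    seed = seed + 1)
      cache <<- list(key = key, records = cur, sequences = sim$sequences,
                     predictions = preds)
    }
    cache
  }
})

# Keys of a record tibble, for aligning predictions with truth in tests.
test_key <- function(df) {
  paste(df$pdb_id, df$position, df$wild_aa, df$mutant_aa)
}
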