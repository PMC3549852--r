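# File I/O: FASTA sequences, curated-dataset TSV + JSON manifest.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file. Record ids are used as-is, so name them
#'   `pdb_id` or `pdb_id_chain` to match mutation tables.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("writing FASTA requires the Biostrings package")
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Write a curated dataset as TSV plus JSON manifest
#'
#' @param records Curated tibble.
#' @param path Output TSV path; the manifest goes to `<path>.manifest.json`
#'   and the rejects (if any) to `<path>.rejects.tsv`.
#' @param name Dataset name recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_curated_dataset <- function(records, path, name = "dataset") {
  cols <- intersect(
    c("pdb_id", "chain", "position", "wild_aa", "mutant_aa", "ph",
      "temperature", "ddg", "label", "window", "ss_class", "rsa_class",
      "superfamily", "source"),
    names(records))
  readr::write_tsv(records[, cols], path, progress = FALSE)
  jsonlite::write_json(dataset_manifest(records, name),
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rej <- mutation_rejects(records)
  if (nrow(rej) > 0) {
    readr::write_tsv(rej, paste0(path, ".rejects.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' Read a curated dataset written by [write_curated_dataset()]
#'
#' @param path TSV path.
#' @return Curated tibble.
#' @export
read_curated_dataset <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pdb_id = "c", chain = "c", position = "i", wild_aa = "c",
    mutant_aa = "c", label = "c", window = "c", .default = "?"),
    progress = FALSE)
}
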