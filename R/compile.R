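# Dataset compilation: ingestion, redundancy removal, sign harmonization,
# labelling, position correction, window extraction, strata annotation.

#' Read a raw mutation table
#'
#' Ingests a TSV/CSV table of single-point mutations. Columns can be renamed
#' through `dialect`, a named character vector (or YAML file, see
#' [read_dialect()]) mapping canonical field names to the file's column names.
#' Canonical fields: `pdb_id`, `chain`, `position`, `wild_aa`, `mutant_aa`,
#' `ph`, `temperature`, `ddg`, `source`, plus optional annotations `ss`, `rsa`,
#' `superfamily`.
#'
#' Rows whose ddG or position fail to parse, whose residue codes are not among
#' the 20 standard amino acids, or where the wild-type equals the mutant
#' residue are skipped and recorded in the rejects table (see
#' [mutation_rejects()]); valid rows keep their file order.
#'
#' @param path Path to a delimited text file. `.csv` is read comma-separated,
#'   anything else tab-separated unless `delim` is given.
#' @param dialect Named character vector `c(canonical = "file_column", ...)`,
#'   or `NULL` when the file already uses canonical names.
#' @param delim Field delimiter override.
#' @return A tibble of raw mutation records with a `rejects` attribute.
#' @export
read_mutation_table <- function(path, dialect = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("mutation table not found: ", path))
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (!is.null(dialect)) {
    missing <- setdiff(unname(dialect), names(raw))
    if (length(missing) > 0) {
      abort(paste0("dialect maps to missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    raw <- rename(raw, !!!setNames(unname(dialect), names(dialect)))
  }
  mandatory <- c("pdb_id", "position", "wild_aa", "mutant_aa", "ddg")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0) {
    abort(paste0("mutation table lacks mandatory column(s): ",
                 paste(absent, collapse = ", ")))
  }
  for (opt in c("chain", "ph", "temperature", "source", "ss", "rsa", "superfamily")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }

  parsed <- tibble(
    pdb_id      = as.character(raw$pdb_id),
    chain       = as.character(raw$chain),
    position    = suppressWarnings(as.integer(raw$position)),
    wild_aa     = toupper(as.character(raw$wild_aa)),
    mutant_aa   = toupper(as.character(raw$mutant_aa)),
    ph          = suppressWarnings(as.numeric(raw$ph)),
    temperature = suppressWarnings(as.numeric(raw$temperature)),
    ddg         = suppressWarnings(as.numeric(raw$ddg)),
    source      = as.character(raw$source),
    ss          = as.character(raw$ss),
    rsa         = suppressWarnings(as.numeric(raw$rsa)),
    superfamily = as.character(raw$superfamily)
  )

  reason <- rep(NA_character_, nrow(parsed))
  bad_ddg <- is.na(parsed$ddg)
  bad_pos <- is.na(parsed$position) | parsed$position < 1
  bad_aa  <- !(parsed$wild_aa %in% standard_aa()) |
             !(parsed$mutant_aa %in% standard_aa())
  same_aa <- !bad_aa & parsed$wild_aa == parsed$mutant_aa
  reason[same_aa] <- "wild_equals_mutant"
  reason[bad_aa]  <- "nonstandard_residue"
  reason[bad_pos] <- "unparseable_position"
  reason[bad_ddg] <- "unparseable_ddg"

  keep <- is.na(reason)
  rejects <- parsed[!keep, ]
  rejects$reason <- reason[!keep]
  records <- parsed[keep, ]
  if (nrow(records) == 0) {
    abort("no valid mutation rows remain after filtering")
  }
  attr(records, "rejects") <- rejects
  records
}

#' Read a column-mapping dialect from YAML
#'
#' @param path YAML file of `canonical: file_column` pairs.
#' @return Named character vector usable as `dialect` in
#'   [read_mutation_table()].
#' @export
read_dialect <- function(path) {
  m <- yaml::read_yaml(path)
  vapply(m, as.character, character(1))
}

#' Rejected rows of an ingestion or labelling step
#'
#' @param x A tibble returned by [read_mutation_table()] or [label_mutations()].
#' @return Tibble of skipped rows with a `reason` column (empty if none).
#' @export
mutation_rejects <- function(x) {
  r <- attr(x, "rejects")
  if (is.null(r)) tibble() else r
}

#' Records dropped by a deduplication or overlap-removal step
#'
#' @param x A tibble returned by [deduplicate_mutations()] or
#'   [remove_overlap()].
#' @return Tibble of removed records (empty if none).
#' @export
removed_records <- function(x) {
  r <- attr(x, "removed")
  if (is.null(r)) tibble() else r
}

#' Remove redundant mutation records
#'
#' Collapses records sharing the same mutation key (PDB id, chain, position,
#' wild-type and mutant residue) to a single record. Replicate measurements
#' that differ only slightly in pH or temperature are duplicates under this
#' key; the first record in input order is kept, the rest are dropped (not
#' averaged).
#'
#' @param records Tibble of mutation records.
#' @return The kept records, input order preserved, with the dropped records
#'   in the `removed` attribute (see [removed_records()]).
#' @export
deduplicate_mutations <- function(records) {
  key <- mutation_key(records)
  keep <- !duplicated(key)
  out <- records[keep, ]
  attr(out, "removed") <- `attr<-`(records[!keep, ], "removed", NULL)
  attr(out, "rejects") <- attr(records, "rejects")
  attr(out, "provenance") <- c(attr(records, "provenance"), "deduplicate")
  out
}

#' Remove records that overlap a reference dataset
#'
#' Drops every record of `records` whose mutation appears in `reference`, so
#' that the two datasets can later be merged without shared training examples.
#' Matching uses (PDB id, position, wild-type, mutant); the chain must agree
#' only when both sides record one.
#'
#' @param records Target tibble (e.g. a newly ingested dataset).
#' @param reference Already-deduplicated reference tibble.
#' @return Kept records with the overlapping ones in the `removed` attribute.
#' @export
remove_overlap <- function(records, reference) {
  tk <- mutation_key_nochain(records)
  rk <- mutation_key_nochain(reference)
  ref_chain <- split(as.character(reference$chain), rk)
  t_chain <- as.character(records$chain)
  hit <- vapply(seq_len(nrow(records)), function(i) {
    rc <- ref_chain[[tk[i]]]
    if (is.null(rc)) return(FALSE)
    any(is.na(rc) | is.na(t_chain[i]) | rc == t_chain[i])
  }, logical(1))
  out <- records[!hit, ]
  attr(out, "removed") <- `attr<-`(records[hit, ], "removed", NULL)
  attr(out, "rejects") <- attr(records, "rejects")
  attr(out, "provenance") <- c(attr(records, "provenance"), "remove_overlap")
  out
}

#' Harmonize the ddG sign convention
#'
#' Under the convention used throughout this package (shared with I-Mutant2.0
#' and AUTO-MUTE), positive ddG means stabilizing. Sources following the
#' PoPMuSiC convention report the opposite sign, so their ddG values are
#' negated. Applying the same call twice restores the original values.
#'
#' @param records Tibble with a `ddg` column.
#' @param convention `"istable"` (identity) or `"popmusic"` (negate).
#' @return The records, ddG harmonized.
#' @export
harmonize_sign <- function(records, convention = c("istable", "popmusic")) {
  convention <- arg_match(convention)
  if (convention == "popmusic") records$ddg <- -records$ddg
  attr(records, "provenance") <-
    c(attr(records, "provenance"), paste0("harmonize_sign:", convention))
  records
}

#' Label mutations as stabilizing or destabilizing
#'
#' @param ddg Numeric vector of ddG values (kcal/mol, stabilizing-positive
#'   convention).
#' @return Character vector: `"POSITIVE"` where ddG > 0, `"NEGATIVE"` where
#'   ddG < 0, `NA` where ddG == 0 (unlabeled — the strict inequalities leave
#'   the boundary undefined, so callers must exclude such records).
#' @export
assign_label <- function(ddg) {
  stopifnot(is.numeric(ddg))
  dplyr::case_when(ddg > 0 ~ "POSITIVE", ddg < 0 ~ "NEGATIVE",
                   .default = NA_character_)
}

#' Attach stability labels to a dataset, rejecting ddG == 0
#'
#' @param records Tibble with a `ddg` column.
#' @return Labelled records; rows with ddG exactly 0 move to the rejects
#'   attribute with reason `"unlabeled"`.
#' @export
label_mutations <- function(records) {
  records$label <- assign_label(records$ddg)
  bad <- is.na(records$label)
  rej <- records[bad, ]
  if (nrow(rej) > 0) {
    rej$label <- NULL
    rej$reason <- "unlabeled"
  }
  out <- records[!bad, ]
  attr(out, "rejects") <- bind_rows(mutation_rejects(records), rej)
  attr(out, "removed") <- attr(records, "removed")
  attr(out, "provenance") <- c(attr(records, "provenance"), "label")
  out
}

#' Find the position offset reconciling records with a sequence
#'
#' Mutation tables sometimes number residues by the structure's absolute
#' numbering while the FASTA sequence is relative (e.g. an initiator Met absent
#' from the deposited sequence). This finds the single shift `d` such that
#' `substr(sequence, position + d, position + d) == wild_aa` for every record
#' of one chain, preferring `d = 0`, then the smallest `|d|` with ties going to
#' the negative shift.
#'
#' @param sequence Protein sequence (single string).
#' @param positions Integer vector of reported 1-based positions.
#' @param wild_aa Character vector of expected wild-type residues.
#' @return The offset `d` (integer scalar).
#' @export
correct_position_offset <- function(sequence, positions, wild_aa) {
  stopifnot(length(positions) == length(wild_aa), length(positions) >= 1,
            nchar(sequence) >= 1)
  len <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  lo <- 1L - min(positions)
  hi <- len - max(positions)
  if (lo > hi) abort("no position offset can place all records inside the sequence")
  cand <- lo:hi
  # preference order: 0, then |d| ascending with negative before positive
  cand <- cand[order(abs(cand), cand)]
  for (d in cand) {
    if (all(chars[positions + d] == wild_aa)) return(as.integer(d))
  }
  # report the first record inconsistent at the best-ranked candidate
  d <- cand[1]
  bad <- which(chars[positions + d] != wild_aa)[1]
  abort(paste0(
    "no offset reconciles all records with the sequence; first inconsistency: ",
    "position ", positions[bad], " expects ", wild_aa[bad]))
}

#' Rewrite reported positions to sequence-relative positions
#'
#' Applies [correct_position_offset()] per (pdb_id, chain) group and shifts
#' that group's positions accordingly.
#'
#' @param records Tibble of mutation records.
#' @param sequences Named character vector of protein sequences; names are
#'   matched as `pdb_id` or `pdb_id_chain`.
#' @return Records with corrected `position`s.
#' @export
apply_position_offsets <- function(records, sequences) {
  grp <- paste(records$pdb_id, ifelse(is.na(records$chain), "", records$chain))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    seqs <- lookup_sequence(sequences, records$pdb_id[idx[1]], records$chain[idx[1]])
    d <- correct_position_offset(seqs, records$position[idx], records$wild_aa[idx])
    records$position[idx] <- records$position[idx] + d
  }
  attr(records, "provenance") <- c(attr(records, "provenance"), "position_offsets")
  records
}

lookup_sequence <- function(sequences, pdb_id, chain) {
  for (nm in c(paste0(pdb_id, "_", chain), pdb_id)) {
    if (!is.na(nm) && nm %in% names(sequences)) return(sequences[[nm]])
  }
  abort(paste0("no sequence found for ", pdb_id,
               if (!is.na(chain)) paste0(" chain ", chain) else ""))
}

#' Extract the sequence window centered on a mutated site
#'
#' Returns the `(window_size - 1)/2` residues on each side of the mutated
#' position plus the site itself. Window positions beyond either terminus are
#' filled with the pad symbol `"-"`, so e.g. position 1 of `"DCAMYWK"` at size
#' 7 yields `"---DCAM"`.
#'
#' @param sequence Protein sequence string (recycled if scalar).
#' @param position 1-based sequence-relative position(s) of the mutation.
#' @param wild_aa Expected wild-type residue(s); mismatch with the sequence is
#'   an error.
#' @param window_size Odd window width (default 11).
#' @return Character vector of windows, each of `nchar` `window_size`.
#' @export
extract_window <- function(sequence, position, wild_aa, window_size = 11) {
  stopifnot(window_size %% 2 == 1, window_size >= 1)
  n <- max(length(sequence), length(position))
  sequence <- rep_len(sequence, n); position <- rep_len(position, n)
  wild_aa <- rep_len(wild_aa, n)
  flank <- (window_size - 1L) / 2L
  found <- substr(sequence, position, position)
  bad <- which(found != wild_aa)
  if (length(bad) > 0) {
    abort(paste0("wild-type mismatch at position ", position[bad[1]],
                 ": expected ", wild_aa[bad[1]], ", found ", found[bad[1]]))
  }
  pad <- strrep("-", flank)
  padded <- paste0(pad, sequence, pad)
  substr(padded, position, position + window_size - 1L)
}

#' Attach sequence windows to a dataset
#'
#' @inheritParams apply_position_offsets
#' @param window_size Odd window width.
#' @return Records with a `window` column.
#' @export
add_windows <- function(records, sequences, window_size = 11) {
  seqs <- vapply(seq_len(nrow(records)), function(i) {
    lookup_sequence(sequences, records$pdb_id[i], records$chain[i])
  }, character(1))
  records$window <- extract_window(seqs, records$position, records$wild_aa,
                                   window_size)
  attr(records, "provenance") <-
    c(attr(records, "provenance"), paste0("windows:", window_size))
  records
}

#' Classify relative solvent accessibility
#'
#' Buried/partially-buried/exposed classes on percent RSA, using half-open
#' bins: `[0, 20)` is `"B"`, `[20, 50)` is `"P"`, `[50, 100]` is `"E"`.
#'
#' @param rsa Numeric vector of percent RSA in `[0, 100]`.
#' @return Character vector over `{"B","P","E"}` (`NA` passes through).
#' @export
classify_rsa <- function(rsa) {
  ok <- is.na(rsa) | (rsa >= 0 & rsa <= 100)
  if (!all(ok)) abort(paste0("RSA outside [0,100]: ", rsa[which(!ok)[1]]))
  dplyr::case_when(is.na(rsa) ~ NA_character_,
                   rsa < 20 ~ "B", rsa < 50 ~ "P", .default = "E")
}

#' Classify a secondary-structure symbol
#'
#' Maps DSSP-style codes onto three classes: H/G/I are helix, E/B are sheet,
#' T/S/C (turn and coil) are other.
#'
#' @param ss_code Character vector of source symbols.
#' @param alphabet Accepted source symbols (default DSSP-style).
#' @return Character vector over `{"helix","sheet","other"}` (`NA` passes
#'   through).
#' @export
classify_ss <- function(ss_code,
                        alphabet = c("H", "G", "I", "E", "B", "T", "S", "C")) {
  known <- is.na(ss_code) | ss_code %in% alphabet
  if (!all(known)) {
    abort(paste0("unknown secondary-structure symbol: ",
                 ss_code[which(!known)[1]]))
  }
  dplyr::case_when(is.na(ss_code) ~ NA_character_,
                   ss_code %in% c("H", "G", "I") ~ "helix",
                   ss_code %in% c("E", "B") ~ "sheet",
                   .default = "other")
}

#' Bin experimental pH and temperature
#'
#' Bins follow the stratified-evaluation grid: lower bounds are inclusive
#' ("<=") so pH 6 falls in the first bin and 37 degrees C in the first
#' temperature bin.
#'
#' @param ph,temperature Numeric vectors.
#' @return Tibble with factor columns `ph_bin` (`<=6`, `6-8`, `>8`) and
#'   `temp_bin` (`<=37`, `37-65`, `>65`).
#' @export
bin_condition <- function(ph, temperature) {
  tibble(
    ph_bin = cut(ph, c(-Inf, 6, 8, Inf), labels = c("<=6", "6-8", ">8"),
                 right = TRUE),
    temp_bin = cut(temperature, c(-Inf, 37, 65, Inf),
                   labels = c("<=37", "37-65", ">65"), right = TRUE)
  )
}

#' Merge two key-disjoint curated datasets
#'
#' @param a,b Curated tibbles; any shared mutation key is an error (run
#'   [remove_overlap()] first).
#' @param name Name for the merged dataset's manifest.
#' @return Concatenated tibble carrying a manifest attribute (see
#'   [dataset_manifest()]).
#' @export
merge_datasets <- function(a, b, name = "merged") {
  if (nrow(b) > 0 && nrow(a) > 0) {
    clash <- nrow(b) - nrow(remove_overlap(b, a))
    if (clash > 0) {
      abort(paste0("datasets share ", clash,
                   " mutation key(s); remove overlap before merging"))
    }
  }
  out <- bind_rows(a, b)
  attr(out, "provenance") <- c(attr(a, "provenance"),
                               paste0("merge:", nrow(a), "+", nrow(b)))
  attr(out, "manifest") <- dataset_manifest(out, name)
  out
}

#' Summarize a curated dataset
#'
#' @param records Curated tibble (labelled).
#' @param name Dataset name.
#' @return A list: `name`, `n_records`, `n_proteins`, `n_positive`,
#'   `n_negative`, `provenance`.
#' @export
dataset_manifest <- function(records, name = "dataset") {
  list(
    name = name,
    n_records = nrow(records),
    n_proteins = dplyr::n_distinct(records$pdb_id),
    n_positive = sum(records$label == "POSITIVE", na.rm = TRUE),
    n_negative = sum(records$label == "NEGATIVE", na.rm = TRUE),
    provenance = as.character(attr(records, "provenance") %||% character())
  )
}

#' Run the full compilation pipeline on one raw dataset
#'
#' Sign harmonization, deduplication, optional overlap removal against a
#' reference, labelling (ddG == 0 rejected), position-offset correction,
#' window extraction, and SS/RSA annotation classification, in that order.
#'
#' @param records Raw mutation tibble (from [read_mutation_table()] or
#'   [simulate_dataset()]).
#' @param sequences Named character vector of protein sequences.
#' @param window_size Odd window width.
#' @param convention ddG sign convention of the source.
#' @param overlap_ref Optional curated reference dataset.
#' @param dedup Whether to run deduplication.
#' @return Curated tibble with `label`, `window`, `ss_class`, `rsa_class`
#'   columns and rejects/removed/provenance attributes.
#' @export
compile_mutations <- function(records, sequences, window_size = 11,
                              convention = c("istable", "popmusic"),
                              overlap_ref = NULL, dedup = TRUE) {
  out <- harmonize_sign(records, convention)
  removed <- tibble()
  if (dedup) {
    out <- deduplicate_mutations(out)
    removed <- bind_rows(removed, removed_records(out))
  }
  if (!is.null(overlap_ref)) {
    out <- remove_overlap(out, overlap_ref)
    removed <- bind_rows(removed, removed_records(out))
  }
  out <- label_mutations(out)
  out <- apply_position_offsets(out, sequences)
  out <- add_windows(out, sequences, window_size)
  if ("ss" %in% names(out)) out$ss_class <- classify_ss(out$ss)
  if ("rsa" %in% names(out)) out$rsa_class <- classify_rsa(out$rsa)
  attr(out, "removed") <- removed
  out
}
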