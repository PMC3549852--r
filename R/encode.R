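# Feature encoding: sequence scheme (one-hot window + mutant residue) and
# website-result scheme (one 3-state block per element predictor).

#' One-hot encode a residue symbol
#'
#' @param symbol A single character from the 21-symbol alphabet
#'   ([aa_alphabet()]: 20 amino acids plus the terminal pad `"-"`).
#' @return Numeric 0/1 vector of length 21 with a single 1 at the symbol's
#'   alphabet index.
#' @export
#' @examples
#' which(encode_residue("A") == 1) # 1
#' which(encode_residue("-") == 1) # 21
encode_residue <- function(symbol) {
  i <- match(symbol, aa_alphabet())
  if (length(symbol) != 1 || is.na(i)) {
    abort(paste0("unknown residue symbol: ", paste(symbol, collapse = "")))
  }
  v <- numeric(21)
  v[i] <- 1
  v
}

#' Encode the sequence scheme for one mutation
#'
#' Concatenates one 21-bit one-hot block per window position followed by one
#' block for the mutant residue, giving `21 * (window_size + 1)` features.
#'
#' @param window Sequence window string (odd length, pad symbol allowed).
#' @param mutant_aa Mutant residue (one of the 20 amino acids; the pad symbol
#'   is not a legal mutant).
#' @return Numeric 0/1 vector of length `21 * (nchar(window) + 1)`.
#' @export
encode_sequence_scheme <- function(window, mutant_aa) {
  chars <- strsplit(window, "")[[1]]
  if (length(chars) %% 2 != 1) abort("window length must be odd")
  if (!mutant_aa %in% standard_aa()) {
    abort(paste0("mutant residue must be a standard amino acid, got: ", mutant_aa))
  }
  unlist(lapply(c(chars, mutant_aa), encode_residue), use.names = FALSE)
}

#' Encode an element predictor's call as a 3-state block
#'
#' The block order is (destabilizing, null, stabilizing): `DECREASE` is
#' `1-0-0`, `NULL_PRED` (no answer) is `0-1-0`, `INCREASE` is `0-0-1`.
#'
#' @param call One of `"DECREASE"`, `"NULL_PRED"`, `"INCREASE"`.
#' @return Numeric 0/1 vector of length 3.
#' @export
encode_tristate <- function(call) {
  i <- match(call, call_levels())
  if (length(call) != 1 || is.na(i)) {
    abort(paste0("unknown call token: ", paste(call, collapse = "")))
  }
  v <- numeric(3)
  v[i] <- 1
  v
}

#' Block layout of a feature mode
#'
#' Describes every block of the feature vector so that encodings are
#' self-documenting and losslessly decodable, and so a trained model can
#' refuse queries encoded under a different layout.
#'
#' @param mode Feature mode name (see [feature_mode()]).
#' @param window_size Window width used by the sequence scheme.
#' @return Tibble with columns `block` (label), `kind`
#'   (`window`/`mutant`/`predictor`), `start`, `length`.
#' @export
feature_layout <- function(mode = "seq_ws", window_size = 11) {
  fm <- feature_mode(mode)
  blocks <- tibble(block = character(), kind = character(), length = integer())
  if (fm$use_sequence) {
    blocks <- bind_rows(
      tibble(block = paste0("win", seq_len(window_size)), kind = "window",
             length = 21L),
      tibble(block = "mutant", kind = "mutant", length = 21L)
    )
  }
  blocks <- bind_rows(
    blocks,
    tibble(block = fm$predictors, kind = "predictor", length = 3L)
  )
  blocks$start <- cumsum(c(1L, blocks$length[-nrow(blocks)]))
  out <- blocks[, c("block", "kind", "start", "length")]
  attr(out, "mode") <- fm$mode
  attr(out, "window_size") <- if (fm$use_sequence) as.integer(window_size) else NA_integer_
  out
}

#' Assemble one feature vector from its blocks
#'
#' @param seq Sequence-scheme vector from [encode_sequence_scheme()], or
#'   `NULL` for `ws_only` mode.
#' @param calls Named character vector of predictor calls; must cover exactly
#'   the predictors of the mode, in canonical order.
#' @param mode Feature mode name.
#' @param window_size Window width (checked against `seq`).
#' @return Numeric feature vector with the layout as attribute `layout`.
#' @export
assemble_features <- function(seq = NULL, calls, mode = "seq_ws",
                              window_size = 11) {
  fm <- feature_mode(mode)
  if (fm$use_sequence) {
    if (is.null(seq)) abort(paste0("mode ", mode, " requires a sequence-scheme vector"))
    if (length(seq) != 21 * (window_size + 1)) {
      abort("sequence-scheme vector length does not match window_size")
    }
  } else {
    seq <- numeric(0)
  }
  if (!identical(names(calls), fm$predictors)) {
    abort(paste0("calls must name exactly: ",
                 paste(fm$predictors, collapse = ", "),
                 " (in that order)"))
  }
  v <- c(seq, unlist(lapply(unname(calls), encode_tristate), use.names = FALSE))
  attr(v, "layout") <- feature_layout(mode, window_size)
  v
}

#' Decode a feature vector back to window, mutant residue and calls
#'
#' Inverse of the encoding: a lossless round-trip is guaranteed for any vector
#' produced by [assemble_features()] or [encode_features()].
#'
#' @param v Numeric feature vector (one row of a feature matrix).
#' @param layout Layout tibble from [feature_layout()].
#' @return List with `window` (string or `NULL`), `mutant_aa` (or `NULL`) and
#'   `calls` (named character vector).
#' @export
decode_features <- function(v, layout) {
  sym <- function(start, len, alphabet) alphabet[which(v[start + 0:(len - 1)] == 1)]
  win <- layout[layout$kind == "window", ]
  mut <- layout[layout$kind == "mutant", ]
  prd <- layout[layout$kind == "predictor", ]
  list(
    window = if (nrow(win) > 0) {
      paste(vapply(seq_len(nrow(win)), function(i)
        sym(win$start[i], 21L, aa_alphabet()), character(1)), collapse = "")
    },
    mutant_aa = if (nrow(mut) > 0) sym(mut$start, 21L, aa_alphabet()),
    calls = setNames(vapply(seq_len(nrow(prd)), function(i)
      sym(prd$start[i], 3L, call_levels()), character(1)), prd$block)
  )
}

#' Encode a curated dataset into a feature matrix
#'
#' Vectorized encoder for model training: one row per record, columns laid out
#' per [feature_layout()]. Predictor calls are looked up in `predictions` by
#' mutation key; a mutation/predictor pair absent from the repository encodes
#' as a null prediction (`0-1-0`).
#'
#' @param records Curated tibble with `window` and `mutant_aa` columns (window
#'   required unless `mode = "ws_only"`).
#' @param predictions Prediction repository tibble (see
#'   [simulate_predictions()] / [read_predictions()]); may be `NULL` for
#'   sequence-only encodings with no predictors — but every mode here uses at
#'   least two predictors, so normally required.
#' @param mode Feature mode name.
#' @return An object of class `stab_features`: list with the numeric matrix
#'   `x`, the `layout`, `mode`, `window_size`, and the records' mutation keys.
#' @export
encode_features <- function(records, predictions = NULL, mode = "seq_ws") {
  fm <- feature_mode(mode)
  n <- nrow(records)
  window_size <- NA_integer_
  blocks <- list()
  if (fm$use_sequence) {
    if (!"window" %in% names(records) || anyNA(records$window)) {
      abort("records must carry a sequence window for this mode")
    }
    ws <- unique(nchar(records$window))
    if (length(ws) != 1) abort("all windows must share one window size")
    window_size <- as.integer(ws)
    for (p in seq_len(window_size)) {
      blocks[[length(blocks) + 1]] <-
        onehot_block(substr(records$window, p, p), aa_alphabet())
    }
    blocks[[length(blocks) + 1]] <- onehot_block(records$mutant_aa, aa_alphabet())
  }
  key <- mutation_key(records)
  for (p in fm$predictors) {
    calls <- rep("NULL_PRED", n)
    if (!is.null(predictions)) {
      pr <- predictions[predictions$predictor == p, ]
      idx <- match(key, mutation_key(pr))
      calls[!is.na(idx)] <- pr$call[idx[!is.na(idx)]]
    }
    blocks[[length(blocks) + 1]] <- onehot_block(calls, call_levels())
  }
  x <- do.call(cbind, blocks)
  layout <- feature_layout(mode, if (is.na(window_size)) 11 else window_size)
  colnames(x) <- unlist(mapply(function(b, l) paste0(b, ".", seq_len(l)),
                               layout$block, layout$length, SIMPLIFY = FALSE))
  structure(
    list(x = x, layout = layout, mode = mode, window_size = window_size,
         key = key),
    class = "stab_features"
  )
}

# n x length(alphabet) one-hot matrix for a character vector.
onehot_block <- function(symbols, alphabet) {
  i <- match(symbols, alphabet)
  if (anyNA(i)) {
    abort(paste0("unknown symbol in encoding: ", symbols[which(is.na(i))[1]]))
  }
  m <- matrix(0, nrow = length(symbols), ncol = length(alphabet))
  m[cbind(seq_along(symbols), i)] <- 1
  m
}

#' @export
print.stab_features <- function(x, ...) {
  cat("<stab_features> ", nrow(x$x), " records x ", ncol(x$x), " features (mode ",
      x$mode, if (!is.na(x$window_size)) paste0(", window ", x$window_size),
      ")\n", sep = "")
  invisible(x)
}

#' Write a feature matrix in sparse LIBSVM format
#'
#' One line per record: the label (`+1` stabilizing, `-1` destabilizing)
#' followed by `index:value` pairs for the non-zero features, 1-based.
#'
#' @param features A `stab_features` object.
#' @param labels Character vector of `"POSITIVE"`/`"NEGATIVE"` labels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_libsvm <- function(features, labels, path) {
  stopifnot(inherits(features, "stab_features"),
            length(labels) == nrow(features$x))
  lab <- ifelse(labels == "POSITIVE", "+1", "-1")
  lines <- vapply(seq_len(nrow(features$x)), function(i) {
    nz <- which(features$x[i, ] != 0)
    paste(lab[i], paste0(nz, ":", features$x[i, nz], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature matrix as dense TSV
#'
#' @inheritParams write_libsvm
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, labels, path) {
  df <- as_tibble(features$x)
  df <- dplyr::bind_cols(tibble(label = labels), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
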