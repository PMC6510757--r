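#' Build a sequence table
#'
#' The package's basic currency is a tibble with one row per sequence and
#' columns `id` (unique identifier) and `seq` (DNA string over A/C/G/T/N).
#' `seq_tbl()` assembles and normalizes such a table from vectors;
#' [read_fasta()] builds one from a FASTA file.
#'
#' Normalization uppercases the sequence and maps U to T (RNA input is
#' accepted under the DNA convention used throughout). Any other character
#' is an error naming the offending symbol. Duplicated ids are made unique
#' deterministically by suffixing `#2`, `#3`, ...
#'
#' @param id Character vector of identifiers.
#' @param seq Character vector of nucleotide sequences (same length as `id`).
#' @return A tibble with columns `id`, `seq`, `length`.
#' @examples
#' seq_tbl("x", "acgu")   # normalized to ACGT
#' @export
seq_tbl <- function(id, seq) {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.")
  }
  x <- tibble(id = as.character(id), seq = as.character(seq))
  normalize_sequences(x)
}

#' Normalize a sequence table
#'
#' Uppercases sequences, maps U to T, validates the A/C/G/T/N alphabet and
#' deduplicates ids (deterministic `#k` suffixes).
#'
#' @param x A data frame with columns `id` and `seq`.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
normalize_sequences <- function(x) {
  check_seq_cols(x)
  seq <- chartr("u", "t", toupper(x$seq))
  seq <- chartr("U", "T", seq)
  bad <- stringr::str_locate(seq, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    sym <- substr(seq[i], bad[i], bad[i])
    abort(sprintf(
      "Sequence '%s' contains disallowed symbol '%s' at position %d (after normalization).",
      x$id[i], sym, bad[i]))
  }
  id <- as.character(x$id)
  if (anyDuplicated(id)) {
    dup <- ave(seq_along(id), id, FUN = seq_along)
    id <- ifelse(dup > 1L, paste0(id, "#", dup), id)
  }
  tibble(id = id, seq = seq, length = nchar(seq))
}

check_seq_cols <- function(x) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("Expected a data frame with columns `id` and `seq`.")
  }
  invisible(x)
}

#' Extract a terminal window from each sequence
#'
#' Returns the last (3' end) or first (5' end) `window` nucleotides of every
#' sequence, clamped to the sequence length. The recognition models in this
#' package are trained on such terminal 50-bp windows. Provenance is recorded
#' in the id (`|3p50` / `|5p50` suffix); the original id and the 0-based
#' offset of the window within the source sequence are kept as columns.
#'
#' @param x A sequence table (see [seq_tbl()]).
#' @param end `"three_prime"` (default) or `"five_prime"`.
#' @param window Window width in nt (default 50).
#' @return A tibble with columns `id`, `seq`, `length`, `source_id`, `offset`.
#' @export
extract_terminal_window <- function(x, end = c("three_prime", "five_prime"),
                                    window = 50L) {
  end <- match.arg(end)
  x <- normalize_sequences(x)
  if (any(x$length == 0L)) abort("Cannot window an empty sequence.")
  w <- pmin(as.integer(window), x$length)
  if (end == "three_prime") {
    offset <- x$length - w
    seq <- substr(x$seq, offset + 1L, x$length)
    tag <- "3p"
  } else {
    offset <- rep(0L, nrow(x))
    seq <- substr(x$seq, 1L, w)
    tag <- "5p"
  }
  tibble(id = paste0(x$id, "|", tag, window), seq = seq, length = w,
         source_id = x$id, offset = as.integer(offset))
}

#' Reverse complement of a sequence table
#'
#' @param x A sequence table.
#' @return `x` with every sequence reverse-complemented (N preserved).
#' @export
reverse_complement <- function(x) {
  x <- normalize_sequences(x)
  x$seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x$seq)))
  x
}
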