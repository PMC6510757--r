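#' Read sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file into a sequence
#' table, preserving record order and normalizing case and U/T.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    abort(sprintf("Malformed FASTA '%s': %s", path,
                                  conditionMessage(e)))
                  })
  if (length(set) == 0L) abort(sprintf("FASTA '%s' contains no records.", path))
  if (any(Biostrings::width(set) == 0L)) {
    abort(sprintf("FASTA '%s' contains a blank record ('%s').", path,
                  names(set)[Biostrings::width(set) == 0L][1]))
  }
  ids <- sub("\\s.*$", "", names(set))
  x <- normalize_sequences(tibble(id = ids,
                                  seq = unname(as.character(set))))
  inform(sprintf("Read %d sequence(s) from '%s'.", nrow(x), path))
  x
}

#' Write a sequence table to FASTA
#'
#' @param x A sequence table (columns `id`, `seq`).
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  check_seq_cols(x)
  set <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write hairpin annotations as TSV or BED6
#'
#' The BED6 representation covers each hairpin's full span with
#' `name = stem:loop:mismatches`, `score = stem_length` and strand `+`
#' (0-based half-open, the native coordinate convention of this package).
#'
#' @param annotations A hairpin annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stemloop_tsv <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_stemloop_tsv
#' @export
write_stemloop_bed <- function(annotations, path) {
  bed <- tibble(
    chrom = annotations$seq_id,
    start = annotations$left_start,
    end = annotations$right_end,
    name = paste(annotations$stem_length,
                 annotations$loop_end - annotations$loop_start,
                 annotations$mismatch_count, sep = ":"),
    score = annotations$stem_length,
    strand = "+")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_stemloop_bed()]
#'
#' @param path Path to a BED6 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_stemloop_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  col_types = "ciicic", progress = FALSE)
}

#' Write / read a feature matrix as TSV
#'
#' Column order is preserved exactly (an `id` column, a `label` column when
#' present, then named feature columns); reading restores the `scheme`
#' attribute when given.
#'
#' @param features A feature tibble ([kmer_frequencies()],
#'   [encode_structure()] or [build_dataset()] output).
#' @param path File path.
#' @param scheme Scheme to attach on read (default: guess from the feature
#'   names).
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_tsv <- function(features, path) {
  out <- features
  attr(out, "scheme") <- NULL
  # %.17g guarantees doubles survive the text round trip bit-for-bit
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path, scheme = NULL) {
  # base parser: exact strtod round trip for the %.17g-formatted doubles
  x <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  x <- as_tibble(x)
  if (is.null(scheme)) {
    feats <- setdiff(names(x), c("id", "label"))
    scheme <- if (identical(feats, structure_feature_names())) "structure_sl"
              else if (all(grepl("^[ACGT]+$", feats))) "sequence_kmer"
              else NULL
  }
  attr(x, "scheme") <- scheme
  x
}

#' Write an experiment report as JSON
#'
#' Serializes metrics, curves, importances and the experiment spec (not the
#' forest itself) with full numeric precision and stable key order, so a
#' seeded rerun is byte-identical.
#'
#' @param experiment An `sl_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(experiment, path) {
  stopifnot(inherits(experiment, "sl_experiment"))
  g <- generics::glance(experiment)
  rep <- list(
    name = experiment$name,
    scheme = experiment$scheme,
    spec = experiment$spec,
    class_counts = as.list(experiment$class_counts),
    summary = as.list(g),
    fold_metrics = experiment$metrics,
    roc_curve = experiment$roc_curve,
    pr_curve = experiment$pr_curve,
    importances = experiment$importances,
    top10 = experiment$top10)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
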