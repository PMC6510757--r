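#' Run the full recognition pipeline end-to-end
#'
#' Chains the package's stages with a single seed: obtain positive
#' sequences (a FASTA file, a sequence table, or the synthetic generator),
#' build the negative class by dinucleotide shuffling, reduce both classes
#' to the chosen representation (terminal-window k-mer frequencies, or
#' structure vectors of the selected terminal stem-loops with the
#' eligibility filter applied identically to both classes), train and
#' cross-validate a Random Forest, and write all artifacts to `out_dir`.
#' Two runs with identical inputs and seed produce byte-identical reports.
#'
#' @param input Positive-class input: a FASTA path or a sequence table. If
#'   `NULL`, sequences are generated with [synthesize_stemloop_set()] using
#'   `synthetic` (plus this `seed`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every random stage.
#' @param scheme `"structure_sl"` (default) or `"sequence_kmer"`.
#' @param end Terminal end to analyse (default `"three_prime"`).
#' @param window Terminal window width (default 50).
#' @param params [hairpin_params()] for detection. Default: for the
#'   structure scheme, `hairpin_params(loop_min = 5)` (the structure
#'   representation requires loops of at least 5 nt anyway, so detecting
#'   with that minimum keeps the best compatible hairpin per sequence);
#'   otherwise the standard defaults.
#' @param n_shuffles Shuffled negatives per positive (default 1).
#' @param n_trees,cv_folds,threshold Passed to [run_experiment()].
#' @param synthetic List of arguments for [synthesize_stemloop_set()] when
#'   `input` is `NULL`.
#' @param name Experiment name (default derived from the scheme).
#' @return Invisibly, a list with the `experiment`, the feature `dataset`,
#'   the selected `stemloops` of both classes and the output `paths`.
#' @export
run_pipeline <- function(input = NULL, out_dir, seed,
                         scheme = c("structure_sl", "sequence_kmer"),
                         end = "three_prime", window = 50L,
                         params = NULL, n_shuffles = 1L,
                         n_trees = 2000L, cv_folds = 5L, threshold = 0.5,
                         synthetic = list(n_sequences = 100L), name = NULL) {
  scheme <- match.arg(scheme)
  if (missing(seed)) abort("An explicit `seed` is required.")
  seed <- as.integer(seed)
  if (is.null(params)) {
    params <- if (scheme == "structure_sl") hairpin_params(loop_min = 5L)
              else hairpin_params()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  positives <- if (is.null(input)) {
    do.call(synthesize_stemloop_set, c(synthetic, list(seed = seed)))
  } else if (is.character(input)) {
    read_fasta(input)
  } else {
    normalize_sequences(input)
  }
  pos <- select(positives, "id", "seq")
  negatives <- dinucleotide_shuffle(pos, seed = seed + 100003L,
                                    n_shuffles = n_shuffles)
  paths$shuffled_fasta <- file.path(out_dir, "shuffled.fasta")
  write_fasta(negatives, paths$shuffled_fasta)

  sl <- list(pos = empty_annotation_tbl(), neg = empty_annotation_tbl())
  if (scheme == "structure_sl") {
    # Detection is restricted to the terminal windows (where the models
    # look); coordinates are then lifted back to the source sequences.
    window_stemloops <- function(x) {
      win <- extract_terminal_window(x, end = end, window = window)
      ann <- select_terminal_stemloops(win, find_stem_loops(win, params),
                                       end = end, window = window,
                                       params = params)
      m <- match(ann$seq_id, win$id)
      coord_cols <- c("left_start", "left_end", "loop_start", "loop_end",
                      "right_start", "right_end", "bulge_left_start",
                      "bulge_left_end", "bulge_right_start",
                      "bulge_right_end")
      ann[, coord_cols] <- ann[, coord_cols] + win$offset[m]
      ann$seq_id <- win$source_id[m]
      eligible_stemloops(ann)
    }
    sl$pos <- window_stemloops(pos)
    sl$neg <- window_stemloops(negatives)
    inform(sprintf("Eligible terminal stem-loops: %d/%d positives, %d/%d shuffled.",
                   nrow(sl$pos), nrow(pos), nrow(sl$neg), nrow(negatives)))
    feat_pos <- encode_structure(sl$pos)
    feat_neg <- encode_structure(sl$neg)
    paths$stemloops_pos <- file.path(out_dir, "stemloops_positive.tsv")
    paths$stemloops_neg <- file.path(out_dir, "stemloops_shuffled.tsv")
    write_stemloop_tsv(sl$pos, paths$stemloops_pos)
    write_stemloop_tsv(sl$neg, paths$stemloops_neg)
    paths$stemloops_bed <- file.path(out_dir, "stemloops_positive.bed")
    write_stemloop_bed(sl$pos, paths$stemloops_bed)
  } else {
    feat_pos <- kmer_frequencies(extract_terminal_window(pos, end = end,
                                                         window = window))
    feat_neg <- kmer_frequencies(extract_terminal_window(negatives, end = end,
                                                         window = window))
  }

  dataset <- build_dataset(feat_pos, feat_neg)
  paths$features <- file.path(out_dir, "features.tsv")
  write_feature_tsv(dataset, paths$features)

  exp <- run_experiment(dataset, n_trees = n_trees, cv_folds = cv_folds,
                        seed = seed, threshold = threshold,
                        name = name %||% paste0("pipeline_", scheme))
  paths$report <- file.path(out_dir, "report.json")
  write_report_json(exp, paths$report)

  invisible(list(experiment = exp, dataset = dataset, stemloops = sl,
                 positives = positives, negatives = negatives, paths = paths))
}
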