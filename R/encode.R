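#' K-mer frequency features (sequence-based scheme)
#'
#' Encodes each sequence as frequencies of its overlapping di- and
#' trinucleotides: for each k-mer width `k`, counts of every k-mer over
#' A/C/G/T at step 1 are divided by the number of windows of that width
#' (`length - k + 1`). Windows containing N contribute to the denominator
#' but never to a count. With the default `ks = c(2, 3)` this yields the
#' 80-dimensional sequence-based representation (16 dinucleotide + 64
#' trinucleotide features, lexicographic within each width, dinucleotides
#' first).
#'
#' @param x A sequence table (columns `id`, `seq`).
#' @param ks Integer vector of k-mer widths (default `c(2, 3)`).
#' @return A tibble with an `id` column and one numeric column per k-mer,
#'   carrying attribute `scheme = "sequence_kmer"`.
#' @examples
#' kmer_frequencies(seq_tbl("x", "ACGT"))
#' @export
kmer_frequencies <- function(x, ks = c(2L, 3L)) {
  x <- normalize_sequences(x)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1L)) abort("`ks` must be positive integers.")
  dss <- Biostrings::DNAStringSet(x$seq)
  blocks <- lapply(ks, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(dss, width = k, step = 1L)
    stopifnot(identical(colnames(counts), .sl_kmers(k)))
    denom <- x$length - k + 1L
    short <- denom < 1L
    if (any(short)) {
      warn(sprintf("%d sequence(s) shorter than %d nt: their %d-mer features are all zero.",
                   sum(short), k, k))
      denom[short] <- 1L
      counts[short, ] <- 0L
    }
    counts / denom
  })
  mat <- do.call(cbind, blocks)
  out <- bind_cols(tibble(id = x$id), as_tibble(mat))
  attr(out, "scheme") <- "sequence_kmer"
  out
}

# One-hot encode a vector of single characters over (A, C, G, T); N (or any
# other symbol) yields an all-zero quartet.
one_hot_base <- function(chars) {
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, .SL_BASES))
  hit <- match(chars, .SL_BASES)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

#' One-hot encoding of loop positions LP0-LP4
#'
#' Encodes the first five loop positions (5' to 3'), each as a one-hot
#' quartet over (A, C, G, T), giving the 20 binary loop features. Loops
#' longer than five nucleotides are truncated to their first five positions;
#' shorter loops are an error (such hairpins are excluded upstream, see
#' [eligible_stemloops()]). An N yields an all-zero quartet.
#'
#' @param loop Character vector of loop strings, each of length >= 5.
#' @return A numeric matrix with one row per loop and 20 columns named
#'   `LP0:A` ... `LP4:T`.
#' @examples
#' encode_loop("GGATA")  # the eel LINE loop motif GGAUA, DNA spelling
#' @export
encode_loop <- function(loop) {
  if (any(nchar(loop) < 5L)) {
    abort(sprintf("Loop '%s' is shorter than 5 nt and cannot be encoded.",
                  loop[which(nchar(loop) < 5L)[1]]))
  }
  blocks <- lapply(0:4, function(p) {
    m <- one_hot_base(substr(loop, p + 1L, p + 1L))
    colnames(m) <- paste0("LP", p, ":", .SL_BASES)
    m
  })
  do.call(cbind, blocks)
}

#' One-hot encoding of bulge positions LB0-LB2 and RB0-RB2
#'
#' Encodes up to three bulge nucleotides per arm as one-hot quartets over
#' (A, C, G, T): slots LB0-LB2 for the left (5') arm bulge, then RB0-RB2 for
#' the right (3') arm bulge, 24 binary features in total. Slots are filled
#' loop-proximal first; positions beyond the bulge length are all zero, so
#' hairpins without bulges encode as 24 zeros.
#'
#' Bulge strings are expected in loop-proximal order. [find_stem_loops()]
#' reports bulges in sequence (5'->3') order, in which the *left*-arm bulge
#' runs away from the loop; [encode_structure()] reverses it accordingly
#' before calling this encoder.
#'
#' @param bulge_left,bulge_right Character vectors of bulge strings in
#'   loop-proximal order, each of length <= 3; `""` for no bulge.
#' @return A numeric matrix with one row per hairpin and 24 columns named
#'   `LB0:A` ... `RB2:T`.
#' @export
encode_bulge <- function(bulge_left, bulge_right = "") {
  n <- max(length(bulge_left), length(bulge_right))
  bulge_left <- rep_len(bulge_left, n)
  bulge_right <- rep_len(bulge_right, n)
  too_long <- nchar(bulge_left) > 3L | nchar(bulge_right) > 3L
  if (any(too_long)) {
    abort("Bulges longer than 3 nt cannot be encoded.")
  }
  slot <- function(s, p, label) {
    m <- one_hot_base(substr(s, p + 1L, p + 1L))  # "" beyond length -> zeros
    colnames(m) <- paste0(label, p, ":", .SL_BASES)
    m
  }
  do.call(cbind, c(lapply(0:2, function(p) slot(bulge_left, p, "LB")),
                   lapply(0:2, function(p) slot(bulge_right, p, "RB"))))
}

#' Dinucleotide-property encoding of stem positions LS0-LS8
#'
#' Takes the ten loop-proximal paired nucleotides of the 5' (left) stem arm,
#' maps T to U, and slides a width-2 window at step 1 to obtain nine
#' dinucleotide steps, indexed LS0 (adjacent to the loop) through LS8
#' (loop-distal). Each step contributes the ten property values from the
#' dinucleotide table in fixed property order, step-major, for 90 numeric
#' features. A step containing N contributes ten zeros (with a warning).
#'
#' @param paired_left Character vector of 5'-arm paired strings (bulges
#'   excluded, 5'->3', ending at the loop), each of length >= 10.
#' @param table A property table from [dinuc_property_table()].
#' @return A numeric matrix with one row per stem and 90 columns named
#'   `LS0:shift` ... `LS8:hydrophilicity`.
#' @examples
#' encode_stem("GCGCGCGCGC")[, 1:4]
#' @export
encode_stem <- function(paired_left, table = dinuc_property_table()) {
  table <- validate_property_table(table)
  if (any(nchar(paired_left) < 10L)) {
    abort("Paired stems shorter than 10 nt cannot be encoded.")
  }
  arm <- gsub("T", "U", substr(paired_left, nchar(paired_left) - 9L,
                               nchar(paired_left)))
  vals <- as.matrix(table[, .SL_PROPERTIES])
  rownames(vals) <- table$dinucleotide
  n_missing <- 0L
  blocks <- lapply(0:8, function(s) {
    # LS_s spans arm positions (9-s, 10-s), 1-based, read 5'->3'.
    step <- substr(arm, 9L - s, 10L - s)
    hit <- match(step, table$dinucleotide)
    m <- matrix(0, nrow = length(step), ncol = 10L)
    ok <- !is.na(hit)
    m[ok, ] <- vals[hit[ok], , drop = FALSE]
    n_missing <<- n_missing + sum(!ok)
    colnames(m) <- paste0("LS", s, ":", .SL_PROPERTIES)
    m
  })
  if (n_missing > 0L) {
    warn(sprintf("%d stem step(s) contained N; their property values were set to 0.",
                 n_missing))
  }
  do.call(cbind, blocks)
}

#' Filter hairpin annotations eligible for structure encoding
#'
#' The structure-based representation requires a paired stem of at least 10
#' nt, a loop of at least 5 nt, and bulges of at most 3 nt. This filter is
#' applied identically to positive and shuffled negative classes, so the
#' classifier cannot learn the filter itself.
#'
#' @param annotations A hairpin annotation tibble ([find_stem_loops()]).
#' @return The eligible subset of `annotations`.
#' @export
eligible_stemloops <- function(annotations) {
  filter(annotations,
         nchar(.data$paired_left) >= 10L,
         .data$loop_end - .data$loop_start >= 5L,
         nchar(.data$bulge_left) <= 3L,
         nchar(.data$bulge_right) <= 3L)
}

#' Structure-based feature vectors (134 features per hairpin)
#'
#' Concatenates the three structural blocks for each hairpin annotation:
#' 90 stem dinucleotide-property features ([encode_stem()]), 20 loop one-hot
#' features ([encode_loop()]) and 24 bulge one-hot features
#' ([encode_bulge()]), with globally unique names of the form
#' `position:property` (e.g. `LS0:shift`, `LP2:G`, `RB1:T`).
#'
#' Hairpins must be eligible (paired stem >= 10 nt, loop >= 5 nt, bulges
#' <= 3 nt); filter with [eligible_stemloops()] first.
#'
#' @param annotations A hairpin annotation tibble ([find_stem_loops()]).
#' @param table A property table from [dinuc_property_table()].
#' @return A tibble with columns `id` (the sequence id) and 134 numeric
#'   feature columns, carrying attribute `scheme = "structure_sl"`.
#' @export
encode_structure <- function(annotations, table = dinuc_property_table()) {
  elig <- eligible_stemloops(annotations)
  if (nrow(elig) != nrow(annotations)) {
    bad <- setdiff(annotations$seq_id, elig$seq_id)
    abort(sprintf(
      "%d annotation(s) are not eligible for structure encoding (need paired stem >= 10, loop >= 5, bulges <= 3); first offender: '%s'. Filter with eligible_stemloops().",
      nrow(annotations) - nrow(elig), bad[1] %||% annotations$seq_id[1]))
  }
  if (nrow(annotations) == 0L) {
    out <- bind_cols(tibble(id = character()),
                     as_tibble(matrix(numeric(0), nrow = 0, ncol = 134,
                                      dimnames = list(NULL, structure_feature_names()))))
    attr(out, "scheme") <- "structure_sl"
    return(out)
  }
  rev_str <- function(s) {
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
  }
  mat <- cbind(encode_stem(annotations$paired_left, table),
               encode_loop(annotations$loop_seq),
               # the left-arm bulge reads loop-proximal 3'->5', so reverse it
               encode_bulge(rev_str(annotations$bulge_left),
                            annotations$bulge_right))
  stopifnot(ncol(mat) == 134L)
  out <- bind_cols(tibble(id = annotations$seq_id), as_tibble(mat))
  attr(out, "scheme") <- "structure_sl"
  out
}

#' Feature names of the structure-based scheme, in order
#' @return Character vector of the 134 structure feature names.
#' @export
structure_feature_names <- function() {
  c(as.vector(t(outer(paste0("LS", 0:8), .SL_PROPERTIES, paste, sep = ":"))),
    as.vector(t(outer(paste0("LP", 0:4), .SL_BASES, paste, sep = ":"))),
    as.vector(t(outer(c(paste0("LB", 0:2), paste0("RB", 0:2)),
                      .SL_BASES, paste, sep = ":"))))
}
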