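# Shared fixtures and small independent oracles used across the test files.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Perfect hairpin string: arm + loop + reverse complement of arm.
hairpin_str <- function(arm, loop) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(arm)))
  paste0(arm, loop, rc)
}

# Overlapping dinucleotide counts by direct substring extraction.
dinuc_counts <- function(s) {
  n <- nchar(s)
  table(substring(s, 1:(n - 1), 2:n))
}

# Naive k-mer frequency oracle: count windows by substring, skip windows with
# N in the numerator, divide by the total window count.
naive_kmer_freq <- function(s, k) {
  n <- nchar(s)
  kmers <- sort(do.call(paste0, expand.grid(rep(list(BASES), k))[, k:1,
                                                                drop = FALSE]))
  counts <- setNames(numeric(length(kmers)), kmers)
  if (n >= k) {
    wins <- substring(s, 1:(n - k + 1), k:n)
    wins <- wins[!grepl("N", wins, fixed = TRUE)]
    tb <- table(wins)
    counts[names(tb)] <- as.numeric(tb)
    counts <- counts / (n - k + 1)
  }
  counts
}

# All sequences reachable by re-walking the dinucleotide multigraph: the
# exact outcome set a dinucleotide-preserving shuffle may produce.
enumerate_dinuc_walks <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  edges <- paste0(ch[-n], ch[-1])
  out <- character(0)
  recurse <- function(cur, remaining, acc) {
    if (length(remaining) == 0) {
      out <<- c(out, paste(acc, collapse = ""))
      return(invisible())
    }
    avail <- unique(remaining[substr(remaining, 1, 1) == cur])
    for (e in avail) {
      idx <- match(e, remaining)
      recurse(substr(e, 2, 2), remaining[-idx], c(acc, substr(e, 2, 2)))
    }
  }
  recurse(ch[1], edges, ch[1])
  sort(unique(out))
}

# Independent re-implementation of the terminal-selection ranking.
rank_terminal_oracle <- function(ann, seq_len, end = "three_prime",
                                 window = 50L) {
  if (end == "three_prime") {
    ann <- ann[ann$left_start >= seq_len - window, , drop = FALSE]
    prox <- -ann$right_end
  } else {
    ann <- ann[ann$right_end <= window, , drop = FALSE]
    prox <- ann$left_start
  }
  if (nrow(ann) == 0) return(ann)
  ord <- order(-ann$stem_length, ann$mismatch_count, prox, ann$loop_start)
  ann[ord[1], , drop = FALSE]
}

# Count positions where paired_left fails to reverse-complement paired_right
# (optionally allowing G:T wobble).
arm_mismatches <- function(left, right, wobble = FALSE) {
  l <- strsplit(left, "", fixed = TRUE)[[1]]
  r <- rev(strsplit(right, "", fixed = TRUE)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- comp[l] == r
  if (wobble) ok <- ok | (l == "G" & r == "T") | (l == "T" & r == "G")
  sum(!ok, na.rm = TRUE) + sum(is.na(ok))
}

# Random feature tibble for experiment tests.
random_features <- function(n, p = 20, mu = 0, tag = "s",
                            scheme = "sequence_kmer") {
  m <- matrix(stats::rnorm(n * p, mean = mu), n, p,
              dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
  out <- dplyr::bind_cols(tibble::tibble(id = paste0(tag, seq_len(n))),
                          tibble::as_tibble(m))
  attr(out, "scheme") <- scheme
  out
}

# Minimal stand-in experiment object for importance-tally tests.
experiment_stub <- function(top10, scheme = "structure_sl") {
  structure(list(scheme = scheme, top10 = top10), class = "sl_experiment")
}
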