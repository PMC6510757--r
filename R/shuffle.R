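#' Dinucleotide-preserving sequence shuffling
#'
#' Generates the alternative (negative) class for the recognition models by
#' shuffling each sequence while exactly preserving its multiset of
#' overlapping dinucleotides (hence also its mononucleotide counts, length,
#' and first and last nucleotide). This is the Altschul-Erikson construction:
#' the sequence is viewed as an Eulerian walk on the dinucleotide multigraph;
#' a random "last-edge" arborescence toward the final nucleotide is drawn
#' (resampled until it spans), the remaining edges are permuted uniformly,
#' and the walk is re-emitted. Shuffling destroys longer-range structure -
#' including planted hairpins - without changing low-level composition, so a
#' classifier separating real from shuffled sequences cannot rely on
#' dinucleotide statistics alone.
#'
#' Sequences containing N are shuffled over the full observed alphabet (N is
#' a fifth symbol), preserving N-containing dinucleotide counts.
#'
#' The result is a pure function of (input, `seed`): record `i`, shuffle `k`
#' uses the derived seed `seed + (i-1)*n_shuffles + (k-1)`.
#'
#' @param x A sequence table (columns `id`, `seq`), each sequence of length
#'   >= 2.
#' @param seed Integer seed controlling all randomness.
#' @param n_shuffles Number of shuffled copies per input sequence (default 1).
#' @return A tibble with `n_shuffles` rows per input, ids suffixed
#'   `|shuf<k>`, and the source id in `source_id`.
#' @examples
#' dinucleotide_shuffle(seq_tbl("x", "AACGCA"), seed = 1)
#' @export
dinucleotide_shuffle <- function(x, seed, n_shuffles = 1L) {
  x <- normalize_sequences(x)
  if (missing(seed)) abort("An explicit `seed` is required.")
  seed <- as.integer(seed)
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 1L) abort("`n_shuffles` must be a positive integer.")
  if (any(x$length < 2L)) {
    abort(sprintf("Sequence '%s' is shorter than 2 nt and cannot be dinucleotide-shuffled.",
                  x$id[which(x$length < 2L)[1]]))
  }
  grid <- expand.grid(k = seq_len(n_shuffles), i = seq_len(nrow(x)))
  out <- purrr::map2_chr(grid$i, grid$k, function(i, k) {
    s <- seed + (i - 1L) * n_shuffles + (k - 1L)
    withr::with_seed(s, shuffle_one(x$seq[i]))
  })
  tibble(id = paste0(x$id[grid$i], "|shuf", grid$k), seq = out,
         length = nchar(out), source_id = x$id[grid$i])
}

# One Altschul-Erikson shuffle of a single sequence; uses the current RNG
# state (callers wrap it in withr::with_seed).
shuffle_one <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 2L) return(seq)
  from <- ch[-n]
  to <- ch[-1L]
  sink <- ch[n]
  verts <- unique(ch)
  outs <- lapply(setNames(verts, verts), function(v) to[from == v])

  # Vertices (other than the sink) that have out-edges must reach the sink
  # through their designated last edge.
  # Any vertex with no out-edges occurs only at the final position, i.e. is
  # the sink itself, so every chain of last edges either reaches the sink or
  # cycles among `need_last` vertices.
  need_last <- setdiff(verts[vapply(outs, length, 1L) > 0L], sink)
  last_edge <- character(0)
  if (length(need_last) > 0L) {
    repeat {
      last_edge <- vapply(need_last, function(v) {
        e <- outs[[v]]
        e[[sample.int(length(e), 1L)]]
      }, character(1))
      reaches_sink <- vapply(need_last, function(v) {
        seen <- character(0)
        while (v != sink) {
          if (v %in% seen) return(FALSE)
          seen <- c(seen, v)
          v <- last_edge[[v]]
        }
        TRUE
      }, logical(1))
      if (all(reaches_sink)) break
    }
  }

  # Permute the remaining edges uniformly; append each vertex's last edge.
  lists <- lapply(setNames(verts, verts), function(v) {
    e <- outs[[v]]
    if (v %in% need_last) {
      drop <- match(last_edge[[v]], e)
      e <- e[-drop]
    }
    if (length(e) > 1L) e <- e[sample.int(length(e))]
    if (v %in% need_last) e <- c(e, last_edge[[v]])
    e
  })

  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- ch[1]
  cur <- ch[1]
  for (t in 2:n) {
    nxt <- lists[[cur]][[ptr[[cur]]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[t] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}
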