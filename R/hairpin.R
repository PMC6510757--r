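#' Stem-loop detection parameters
#'
#' Constraint set for the approximate inverted-repeat search: stem length
#' between `stem_min` and `stem_max` paired positions, loop length between
#' `loop_min` and `loop_max` nt, at most `max_mismatches` non-paired stem
#' positions, and at most one bulge run of up to `max_bulge_per_arm` nt per
#' arm. The defaults are the annotation settings used for retrotransposon
#' 3'-end stem-loops: stems of 10-20 bp, loops up to 10 nt, up to 5
#' mismatches. `loop_min` defaults to 3, the shortest sterically sensible
#' hairpin loop. Pairing is canonical Watson-Crick (A:T, C:G) on the DNA
#' alphabet; G:T wobble pairs can be enabled with `allow_wobble`. N never
#' pairs and counts as a mismatch inside a stem.
#'
#' @param stem_min,stem_max Stem length bounds (paired positions per arm).
#' @param loop_min,loop_max Loop length bounds (nt).
#' @param max_mismatches Maximum number of mismatched stem positions.
#' @param max_bulge_per_arm Maximum bulge run length per arm (nt); one
#'   contiguous bulge run at most per arm, strictly interior to the arm.
#' @param allow_wobble Count G:T as a pair (default `FALSE`).
#' @return An object of class `hairpin_params`.
#' @export
hairpin_params <- function(stem_min = 10L, stem_max = 20L,
                           loop_min = 3L, loop_max = 10L,
                           max_mismatches = 5L, max_bulge_per_arm = 3L,
                           allow_wobble = FALSE) {
  p <- list(stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
            loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
            max_mismatches = as.integer(max_mismatches),
            max_bulge_per_arm = as.integer(max_bulge_per_arm),
            allow_wobble = isTRUE(allow_wobble))
  if (p$stem_min < 1L || p$stem_min > p$stem_max) {
    abort("Need 1 <= stem_min <= stem_max.")
  }
  if (p$loop_min < 1L || p$loop_min > p$loop_max) {
    abort("Need 1 <= loop_min <= loop_max.")
  }
  if (p$max_mismatches < 0L || p$max_bulge_per_arm < 0L) {
    abort("max_mismatches and max_bulge_per_arm must be >= 0.")
  }
  structure(p, class = "hairpin_params")
}

#' @export
print.hairpin_params <- function(x, ...) {
  cat(sprintf(
    "<hairpin_params> stem %d-%d bp, loop %d-%d nt, <=%d mismatches, bulge <=%d nt/arm, wobble=%s\n",
    x$stem_min, x$stem_max, x$loop_min, x$loop_max, x$max_mismatches,
    x$max_bulge_per_arm, x$allow_wobble))
  invisible(x)
}

# Shared post-processing: raw C++ candidate table -> full annotation tibble.
annotate_hairpins <- function(raw, id, seq) {
  if (nrow(raw) == 0L) return(empty_annotation_tbl())
  a <- raw$loop_start
  b <- raw$loop_end
  k <- raw$stem_length
  bl <- raw$bulge_left_len
  gl <- raw$bulge_left_offset
  br <- raw$bulge_right_len
  gr <- raw$bulge_right_offset

  left_start <- a - k - bl
  right_end <- b + k + br
  bls <- ifelse(bl > 0L, a - gl - bl, NA_integer_)
  ble <- ifelse(bl > 0L, a - gl, NA_integer_)
  brs <- ifelse(br > 0L, b + gr, NA_integer_)
  bre <- ifelse(br > 0L, b + gr + br, NA_integer_)

  sub0 <- function(from, to) substr(rep(seq, length(from)), from + 1L, to)
  paired_left <- ifelse(bl > 0L,
                        paste0(sub0(left_start, bls), sub0(ble, a)),
                        sub0(left_start, a))
  paired_right <- ifelse(br > 0L,
                         paste0(sub0(b, brs), sub0(bre, right_end)),
                         sub0(b, right_end))
  tibble(
    seq_id = id,
    left_start = as.integer(left_start), left_end = as.integer(a),
    loop_start = as.integer(a), loop_end = as.integer(b),
    right_start = as.integer(b), right_end = as.integer(right_end),
    stem_length = as.integer(k), mismatch_count = as.integer(raw$mismatch_count),
    bulge_left_start = as.integer(bls), bulge_left_end = as.integer(ble),
    bulge_right_start = as.integer(brs), bulge_right_end = as.integer(bre),
    paired_left = paired_left, paired_right = paired_right,
    loop_seq = sub0(a, b),
    bulge_left = ifelse(bl > 0L, sub0(bls, ble), ""),
    bulge_right = ifelse(br > 0L, sub0(brs, bre), ""))
}

empty_annotation_tbl <- function() {
  tibble(
    seq_id = character(), left_start = integer(), left_end = integer(),
    loop_start = integer(), loop_end = integer(), right_start = integer(),
    right_end = integer(), stem_length = integer(), mismatch_count = integer(),
    bulge_left_start = integer(), bulge_left_end = integer(),
    bulge_right_start = integer(), bulge_right_end = integer(),
    paired_left = character(), paired_right = character(),
    loop_seq = character(), bulge_left = character(),
    bulge_right = character())
}

#' Find approximate stem-loops in sequences
#'
#' Searches every sequence for hairpin structures satisfying the constraints
#' in `params`: two arms pairing into a stem (canonical Watson-Crick, with a
#' mismatch budget), a closing loop, and at most one bulge run per arm.
#' The search enumerates every candidate loop interval and bulge layout and
#' extends the stem outward from the loop. A stem must begin and end on a
#' paired position; per loop interval only the best configuration is kept
#' (longest stem, then fewest mismatches, then least bulged); annotations
#' whose paired positions are all contained in another annotation's are
#' dropped, so each reported hairpin is maximal.
#'
#' All coordinates are 0-based, half-open. `paired_left`/`paired_right` are
#' the arm strings with bulge nucleotides excluded, and reverse-complement
#' each other at all but `mismatch_count` positions.
#'
#' @param x A sequence table (columns `id`, `seq`).
#' @param params A [hairpin_params()] object.
#' @return A tibble of annotations, one row per hairpin, sorted by sequence
#'   and loop start.
#' @examples
#' hp <- seq_tbl("hp", paste0("ATTGCACCGGAT", "TTCGA", "ATCCGGTGCAAT"))
#' find_stem_loops(hp)
#' @export
find_stem_loops <- function(x, params = hairpin_params()) {
  stopifnot(inherits(params, "hairpin_params"))
  x <- normalize_sequences(x)
  res <- purrr::map2(x$id, x$seq, function(id, seq) {
    raw <- .hairpin_search_cpp(seq, params$stem_min, params$stem_max,
                               params$loop_min, params$loop_max,
                               params$max_mismatches, params$max_bulge_per_arm,
                               params$allow_wobble)
    annotate_hairpins(as_tibble(raw), id, seq)
  })
  bind_rows(empty_annotation_tbl(), res)
}

#' Brute-force reference stem-loop enumerator
#'
#' Independently coded reference implementation of the hairpin definition
#' used by [find_stem_loops()]: enumerates every (loop, stem, bulge)
#' partition of each sequence and tests the constraints one by one. Used to
#' validate the optimized search; identical output is an invariant of the
#' package's test suite. Orders of magnitude slower - intended for short
#' sequences only.
#'
#' @inheritParams find_stem_loops
#' @return A tibble of annotations in the same format as [find_stem_loops()].
#' @export
stem_loops_exhaustive <- function(x, params = hairpin_params()) {
  stopifnot(inherits(params, "hairpin_params"))
  x <- normalize_sequences(x)
  res <- purrr::map2(x$id, x$seq, function(id, seq) {
    raw <- .hairpin_enum_cpp(seq, params$stem_min, params$stem_max,
                             params$loop_min, params$loop_max,
                             params$max_mismatches, params$max_bulge_per_arm,
                             params$allow_wobble)
    annotate_hairpins(as_tibble(raw), id, seq)
  })
  bind_rows(empty_annotation_tbl(), res)
}

#' Select the terminal stem-loop of each sequence
#'
#' Keeps, per sequence, the single best hairpin whose full span lies inside
#' the terminal window (the last `window` nt for the 3' end, the first
#' `window` nt for the 5' end). Ranking: longer stem, then fewer mismatches,
#' then closer to the selected terminus. Sequences without a qualifying
#' hairpin contribute no row.
#'
#' @param x The sequence table the annotations were computed from.
#' @param annotations Output of [find_stem_loops()].
#' @param end `"three_prime"` (default) or `"five_prime"`.
#' @param window Terminal window width in nt (default 50).
#' @param params The [hairpin_params()] used for detection; only used to
#'   warn when `window` cannot hold any hairpin.
#' @return A tibble of annotations with at most one row per sequence.
#' @export
select_terminal_stemloops <- function(x, annotations,
                                      end = c("three_prime", "five_prime"),
                                      window = 50L,
                                      params = hairpin_params()) {
  end <- match.arg(end)
  x <- normalize_sequences(x)
  min_span <- 2L * params$stem_min + params$loop_min
  if (window < min_span) {
    warn(sprintf("Window (%d nt) is below the minimal hairpin span (%d nt); no stem-loop can qualify.",
                 window, min_span))
    return(empty_annotation_tbl())
  }
  if (nrow(annotations) == 0L) return(empty_annotation_tbl())
  ann <- left_join(annotations, select(x, seq_id = "id", seq_len = "length"),
                   by = "seq_id")
  if (any(is.na(ann$seq_len))) {
    abort("Some annotations reference sequences absent from `x`.")
  }
  if (end == "three_prime") {
    ann <- filter(ann, .data$left_start >= .data$seq_len - window)
    ann <- arrange(ann, .data$seq_id, desc(.data$stem_length),
                   .data$mismatch_count, desc(.data$right_end),
                   .data$loop_start)
  } else {
    ann <- filter(ann, .data$right_end <= window)
    ann <- arrange(ann, .data$seq_id, desc(.data$stem_length),
                   .data$mismatch_count, .data$left_start, .data$loop_start)
  }
  ann |>
    group_by(.data$seq_id) |>
    slice(1L) |>
    ungroup() |>
    select(-"seq_len")
}
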