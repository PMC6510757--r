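#' Generate synthetic sequences with planted terminal stem-loops
#'
#' Seeded generator of fixture sequences for end-to-end testing of the
#' detection / shuffling / encoding / classification pipeline. Background
#' nucleotides are drawn i.i.d. uniform over A/C/G/T (a deliberately clean
#' null; no genome-like composition). With probability `plant_probability` a
#' hairpin is synthesized - left arm sampled (optionally from a dinucleotide
#' bias), right arm its reverse complement, then mismatches and bulges
#' injected - and embedded entirely within the terminal `window` nt of the
#' chosen end. Ground-truth coordinates are returned alongside.
#'
#' Planted hairpins are made exactly recoverable by
#' [find_stem_loops()] + [select_terminal_stemloops()] through three guards:
#' certified plants draw the loop from the mutually non-pairing alphabet
#' A/C (with boundary bases avoiding partners of the adjacent stem bases),
#' so the loop cannot close further pairs; the flanking bases on both sides
#' are drawn from A/C as well, so the stem cannot extend outward - with or
#' without a fresh bulge - within the mismatch budget; and (with
#' `certify = TRUE`) each sequence is re-detected after assembly and
#' resampled until the planted hairpin is exactly the top-ranked terminal
#' stem-loop. With strongly self-similar stems (e.g. a hard GG/CC bias) the
#' planted hairpin can be inherently ambiguous; disable certification there.
#'
#' Mismatches are placed at interior stem positions (a terminal mismatch
#' would, by definition, shorten the detected stem).
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Sequence length in nt (default 300).
#' @param plant_probability Probability that a sequence carries a planted
#'   hairpin (default 1).
#' @param stem_length_range Planted stem length bounds (default c(10, 20)).
#' @param loop_length_range Planted loop length bounds (default c(5, 10)).
#' @param loop_motif Optional fixed loop string (e.g. `"GGATA"`); its length
#'   must lie within `loop_length_range`.
#' @param n_mismatches Mismatches injected per planted stem (default 0).
#' @param bulge_sizes Length-2 integer vector: left/right arm bulge lengths,
#'   each <= 3 (default c(0, 0)).
#' @param stem_dinuc_bias Optional named weights over DNA dinucleotides; the
#'   left arm is then sampled as a first-order chain with transition
#'   probabilities proportional to the weights (unnamed dinucleotides get
#'   weight 0; an all-zero row falls back to uniform).
#' @param plant_window `"three_prime"` (default) or `"five_prime"`.
#' @param window Terminal window width the hairpin must fit in (default 50).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param params [hairpin_params()] used for certification.
#' @param certify Re-detect and resample until the planted hairpin is
#'   exactly recovered (default TRUE).
#' @param max_tries Resampling budget per sequence (default 100).
#' @return A tibble with columns `id`, `seq`, `length`, `planted`, and
#'   ground-truth columns (`left_start`, `left_end`, `loop_start`,
#'   `loop_end`, `right_start`, `right_end`, `stem_length`, `loop_length`,
#'   `mismatch_count`, `bulge_left_len`, `bulge_right_len`; NA when not
#'   planted).
#' @export
synthesize_stemloop_set <- function(n_sequences, seq_length = 300L,
                                    plant_probability = 1,
                                    stem_length_range = c(10L, 20L),
                                    loop_length_range = c(5L, 10L),
                                    loop_motif = NULL,
                                    n_mismatches = 0L,
                                    bulge_sizes = c(0L, 0L),
                                    stem_dinuc_bias = NULL,
                                    plant_window = c("three_prime", "five_prime"),
                                    window = 50L, seed,
                                    params = hairpin_params(),
                                    certify = TRUE, max_tries = 100L) {
  plant_window <- match.arg(plant_window)
  if (missing(seed)) abort("An explicit `seed` is required.")
  seed <- as.integer(seed)
  stem_length_range <- as.integer(stem_length_range)
  loop_length_range <- as.integer(loop_length_range)
  bulge_sizes <- as.integer(bulge_sizes)
  if (!is.null(loop_motif)) {
    loop_motif <- normalize_sequences(tibble(id = "m", seq = loop_motif))$seq
    if (nchar(loop_motif) < loop_length_range[1] ||
        nchar(loop_motif) > loop_length_range[2]) {
      abort("`loop_motif` length must lie within `loop_length_range`.")
    }
  }
  if (stem_length_range[1] < params$stem_min ||
      stem_length_range[2] > params$stem_max ||
      loop_length_range[1] < max(params$loop_min, 1L) ||
      loop_length_range[2] > params$loop_max) {
    abort("Planted stem/loop ranges must lie within the detection constraints in `params`.")
  }
  if (any(bulge_sizes < 0L) || any(bulge_sizes > params$max_bulge_per_arm)) {
    abort("`bulge_sizes` must be within [0, max_bulge_per_arm].")
  }
  if (n_mismatches < 0L || n_mismatches > params$max_mismatches) {
    abort("`n_mismatches` must be within [0, max_mismatches].")
  }
  if (stem_length_range[1] < n_mismatches + 2L) {
    abort("Planted stems need at least n_mismatches + 2 paired positions.")
  }
  if (!is.null(stem_dinuc_bias)) {
    if (is.null(names(stem_dinuc_bias)) ||
        !all(names(stem_dinuc_bias) %in% .SL_DINUCS_DNA) ||
        any(stem_dinuc_bias < 0)) {
      abort("`stem_dinuc_bias` must be nonnegative weights named by DNA dinucleotides.")
    }
  }
  max_span <- 2L * (stem_length_range[2] + max(bulge_sizes)) +
    loop_length_range[2]
  if (max_span > min(seq_length, window)) {
    abort(sprintf("Maximal hairpin span (%d nt) exceeds min(seq_length, window) = %d.",
                  max_span, min(seq_length, window)))
  }

  rows <- purrr::map(seq_len(n_sequences), function(i) {
    withr::with_seed(seed + i, synth_one(
      i, seq_length, plant_probability, stem_length_range, loop_length_range,
      loop_motif, n_mismatches, bulge_sizes, stem_dinuc_bias, plant_window,
      window, params, certify, max_tries))
  })
  bind_rows(rows)
}

# One sequence; uses the current RNG state.
synth_one <- function(i, seq_length, plant_probability, stem_range, loop_range,
                      loop_motif, n_mm, bulges, bias, end, window, params,
                      certify, max_tries) {
  id <- sprintf("synth_%04d", i)
  plant <- stats::runif(1) < plant_probability
  na_truth <- tibble(planted = FALSE, left_start = NA_integer_,
                     left_end = NA_integer_, loop_start = NA_integer_,
                     loop_end = NA_integer_, right_start = NA_integer_,
                     right_end = NA_integer_, stem_length = NA_integer_,
                     loop_length = NA_integer_, mismatch_count = NA_integer_,
                     bulge_left_len = NA_integer_, bulge_right_len = NA_integer_)
  if (!plant) {
    bg <- paste(sample(.SL_BASES, seq_length, replace = TRUE), collapse = "")
    return(bind_cols(tibble(id = id, seq = bg, length = seq_length), na_truth))
  }

  pick_in <- function(rng) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  pick1 <- function(v) v[[sample.int(length(v), 1L)]]
  for (try in seq_len(max_tries)) {
    s <- pick_in(stem_range)
    llen <- if (is.null(loop_motif)) pick_in(loop_range) else nchar(loop_motif)

    left <- sample_arm(s, bias)                      # 5'->3', ends at the loop
    right <- vapply(rev(left), wc_pair, character(1))  # reverse complement

    # Loop guards: no loop base may pair another loop base or the adjacent
    # stem base, or the detector would rightly close further pairs and report
    # a longer stem with a shifted loop. Certified plants therefore draw the
    # loop from the mutually non-pairing alphabet {A, C}; the boundary bases
    # additionally avoid partners of the loop-adjacent arm bases.
    if (is.null(loop_motif)) {
      alpha <- if (certify) c("A", "C") else .SL_BASES
      loop <- sample(alpha, llen, replace = TRUE)
      c1 <- setdiff(alpha, forbidden_partners(right[1]))
      if (left[s] == "G") c1 <- setdiff(c1, "T")
      if (left[s] == "T") c1 <- setdiff(c1, "G")
      loop[1] <- pick1(c1)
      cl <- setdiff(alpha, c(forbidden_partners(loop[1]),
                             forbidden_partners(left[s])))
      loop[llen] <- pick1(cl)
    } else {
      loop <- strsplit(loop_motif, "", fixed = TRUE)[[1]]
      if (loop[llen] %in% forbidden_partners(loop[1])) {
        warn("`loop_motif` ends can pair; the planted loop is not exactly recoverable.")
      }
    }
    # right[1] is loop-adjacent. Pair t (from loop, 0-based) is
    # left[s - t] vs right[t + 1].
    if (n_mm > 0L) {
      tt <- sample(1:(s - 2L), n_mm)
      for (t in tt) {
        l <- left[s - t]
        right[t + 1L] <- sample(setdiff(.SL_BASES, forbidden_partners(l)), 1L)
      }
    }
    bl <- bulges[1]; br <- bulges[2]
    gl <- if (bl > 0L) sample(1:(s - 1L), 1L) else 0L
    gr <- if (br > 0L) sample(1:(s - 1L), 1L) else 0L
    left_full <- append(left, sample(.SL_BASES, bl, replace = TRUE),
                        after = s - gl)
    right_full <- append(right, sample(.SL_BASES, br, replace = TRUE),
                         after = gr)
    hp <- c(left_full, loop, right_full)
    hp_len <- length(hp)

    w <- min(window, seq_length)
    lo <- if (end == "three_prime") seq_length - w else 0L
    hi <- if (end == "three_prime") seq_length - hp_len else w - hp_len
    start <- if (lo >= hi) lo else sample(lo:hi, 1L)

    bg <- sample(.SL_BASES, seq_length, replace = TRUE)
    bg[(start + 1L):(start + hp_len)] <- hp
    a <- start + s + bl          # loop start, 0-based
    b <- a + llen                # loop end

    # Flank guard: the bases a stem extension (with or without a fresh bulge)
    # could recruit are the max_mismatches + max_bulge positions flanking each
    # side of the hairpin. Drawing them from the mutually non-pairing alphabet
    # {A, C} on both sides makes every such pair a mismatch, so no extension
    # can satisfy the terminal-match rule within the mismatch budget.
    for (q in 0:(params$max_mismatches + params$max_bulge_per_arm)) {
      ii <- start - 1L - q
      if (ii >= 0L) bg[ii + 1L] <- pick1(c("A", "C"))
      jj <- start + hp_len + q
      if (jj < seq_length) bg[jj + 1L] <- pick1(c("A", "C"))
    }

    seqstr <- paste(bg, collapse = "")
    truth <- tibble(
      planted = TRUE,
      left_start = as.integer(start), left_end = as.integer(a),
      loop_start = as.integer(a), loop_end = as.integer(b),
      right_start = as.integer(b),
      right_end = as.integer(b + s + br),
      stem_length = as.integer(s), loop_length = as.integer(llen),
      mismatch_count = as.integer(n_mm),
      bulge_left_len = as.integer(bl), bulge_right_len = as.integer(br))

    if (!certify) {
      return(bind_cols(tibble(id = id, seq = seqstr, length = seq_length), truth))
    }
    # Certify on a slack-padded terminal region: any hairpin that could
    # dominate or outrank a window-contained one shares its loop interval (or
    # a window-contained loop), so its span lies within stem_max + max_bulge
    # of the window; detection there is equivalent to full-sequence detection
    # for the terminal verdict, and much cheaper on long sequences.
    slack <- params$stem_max + params$max_bulge_per_arm
    w <- min(window, seq_length)
    if (end == "three_prime") {
      off <- max(0L, seq_length - w - slack)
      region <- substr(seqstr, off + 1L, seq_length)
    } else {
      off <- 0L
      region <- substr(seqstr, 1L, min(seq_length, w + slack))
    }
    x <- tibble(id = id, seq = region)
    det <- select_terminal_stemloops(x, find_stem_loops(x, params), end = end,
                                     window = w, params = params)
    det[, c("left_start", "left_end", "loop_start", "loop_end", "right_start",
            "right_end")] <-
      det[, c("left_start", "left_end", "loop_start", "loop_end",
              "right_start", "right_end")] + off
    if (nrow(det) == 1L &&
        det$left_start == truth$left_start &&
        det$loop_start == truth$loop_start &&
        det$loop_end == truth$loop_end &&
        det$right_end == truth$right_end &&
        det$stem_length == truth$stem_length &&
        det$mismatch_count == truth$mismatch_count) {
      return(bind_cols(tibble(id = id, seq = seqstr, length = seq_length), truth))
    }
  }
  abort(sprintf("Could not certify a recoverable planted hairpin for '%s' in %d tries; relax the plant spec or disable certification.",
                id, max_tries))
}

wc_pair <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# Bases that would pair with `l` (Watson-Crick plus G:T wobble, so guards
# hold whether or not wobble detection is enabled).
forbidden_partners <- function(l) {
  f <- wc_pair(l)
  if (l == "G") f <- c(f, "T")
  if (l == "T") f <- c(f, "G")
  f
}

# Sample a stem arm 5'->3'; with a dinucleotide bias, a first-order chain.
sample_arm <- function(s, bias) {
  if (is.null(bias)) return(sample(.SL_BASES, s, replace = TRUE))
  w <- setNames(rep(0, 16), .SL_DINUCS_DNA)
  w[names(bias)] <- bias
  trans <- matrix(w[paste0(rep(.SL_BASES, each = 4), .SL_BASES)],
                  nrow = 4, byrow = TRUE,
                  dimnames = list(.SL_BASES, .SL_BASES))
  first_w <- rowSums(trans)
  if (sum(first_w) == 0) first_w <- rep(1, 4)
  arm <- character(s)
  arm[1] <- sample(.SL_BASES, 1L, prob = first_w)
  for (p in seq_len(s - 1L)) {
    pw <- trans[arm[p], ]
    if (sum(pw) == 0) pw <- rep(1, 4)
    arm[p + 1L] <- sample(.SL_BASES, 1L, prob = pw)
  }
  arm
}
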