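test_that("homopolymers yield no hairpins and invalid symbols are rejected", {
  expect_identical(nrow(find_stem_loops(seq_tbl("a", strrep("A", 60)))), 0L)
  expect_identical(nrow(find_stem_loops(seq_tbl("e", ""))), 0L)
  expect_error(seq_tbl("x", "ACGTX"), "disallowed symbol 'X' at position 5")
  expect_error(hairpin_params(stem_min = 0), "stem_min")
  expect_error(hairpin_params(loop_min = 7, loop_max = 5), "loop_min")
})

# Expected values below were frozen from the brute-force enumerator
# (stem_loops_exhaustive), which both implementations must reproduce.
test_that("worked stem constructs match enumerator-frozen annotations", {
  perfect <- paste0("ATTGCACCGGAT", "TTCGA", "ATCCGGTGCAAT")
  mutated <- perfect
  substr(mutated, 20, 20) <- "A"  # break the pair at stem position 2
  substr(mutated, 23, 23) <- "A"  # break the pair at stem position 5
  x <- seq_tbl(c("perfect", "mutated"), c(perfect, mutated))

  ann <- find_stem_loops(x)
  expect_identical(nrow(ann[ann$seq_id == "perfect", ]), 4L)
  expect_identical(nrow(ann[ann$seq_id == "mutated", ]), 7L)

  sel <- select_terminal_stemloops(x, ann, window = 50)
  p <- sel[sel$seq_id == "perfect", ]
  expect_identical(p$stem_length, 13L)
  expect_identical(c(p$loop_start, p$loop_end), c(13L, 16L))
  expect_identical(p$mismatch_count, 0L)
  expect_identical(p$paired_left, "ATTGCACCGGATT")
  m <- sel[sel$seq_id == "mutated", ]
  expect_identical(m$stem_length, 13L)
  expect_identical(m$mismatch_count, 2L)

  # A perfect hairpin with 9-bp arms falls below the 10-20 bp stem range.
  short9 <- seq_tbl("short9", paste0("ATTGCACCG", "CACAA", "CGGTGCAAT"))
  expect_identical(nrow(find_stem_loops(short9)), 0L)
  expect_identical(nrow(stem_loops_exhaustive(short9)), 0L)
})

test_that("the banded search equals the brute-force enumerator", {
  withr::local_seed(101)
  param_sets <- list(
    hairpin_params(),
    hairpin_params(allow_wobble = TRUE),
    hairpin_params(max_bulge_per_arm = 0, max_mismatches = 2),
    hairpin_params(stem_min = 8, stem_max = 14, loop_min = 4, loop_max = 8))
  for (params in param_sets) {
    x <- seq_tbl(sprintf("r%02d", 1:15),
                 vapply(1:15, function(i) random_seq(sample(30:60, 1)),
                        character(1)))
    expect_identical(as.data.frame(find_stem_loops(x, params)),
                     as.data.frame(stem_loops_exhaustive(x, params)))
  }
  # N never pairs: sequences with N agree too and report no N in stems' pairs
  xn <- seq_tbl("n1", paste0(substr(random_seq(25), 1, 25), "NN",
                             random_seq(25)))
  expect_identical(as.data.frame(find_stem_loops(xn)),
                   as.data.frame(stem_loops_exhaustive(xn)))
})

test_that("hairpin calls reflect onto the reverse complement", {
  withr::local_seed(77)
  for (i in 1:10) {
    x <- seq_tbl("f", random_seq(55))
    len <- x$length
    fwd <- find_stem_loops(x)
    rev <- find_stem_loops(reverse_complement(x))
    key_fwd <- sort(paste(fwd$loop_start, fwd$loop_end, fwd$stem_length,
                          fwd$mismatch_count))
    key_rev <- sort(paste(len - rev$loop_end, len - rev$loop_start,
                          rev$stem_length, rev$mismatch_count))
    expect_identical(key_fwd, key_rev)
  }
})

test_that("annotation geometry and strings are internally consistent", {
  withr::local_seed(55)
  for (wobble in c(FALSE, TRUE)) {
    params <- hairpin_params(allow_wobble = wobble)
    x <- seq_tbl(paste0("s", 1:10),
                 vapply(1:10, function(i) random_seq(70), character(1)))
    ann <- find_stem_loops(x, params)
    expect_gt(nrow(ann), 0)
    expect_true(all(ann$left_start >= 0 & ann$left_end <= ann$loop_start))
    expect_true(all(ann$loop_end <= ann$right_start))
    expect_true(all(nchar(ann$paired_left) == ann$stem_length))
    expect_true(all(nchar(ann$paired_right) == ann$stem_length))
    expect_true(all(ann$stem_length >= 10 & ann$stem_length <= 20))
    expect_true(all(ann$loop_end - ann$loop_start >= 3 &
                      ann$loop_end - ann$loop_start <= 10))
    expect_true(all(nchar(ann$bulge_left) <= 3 & nchar(ann$bulge_right) <= 3))
    mm <- mapply(arm_mismatches, ann$paired_left, ann$paired_right,
                 MoreArgs = list(wobble = wobble))
    expect_identical(as.integer(unname(mm)), ann$mismatch_count)
  }
})

test_that("relaxing constraints is monotone where maximality permits", {
  withr::local_seed(31)
  x <- seq_tbl(paste0("m", 1:8),
               vapply(1:8, function(i) random_seq(60), character(1)))
  # With a fixed stem length no annotation can dominate another, so the set
  # of reported loop intervals grows monotonically with the mismatch budget.
  loops_at <- function(mm) {
    ann <- find_stem_loops(x, hairpin_params(stem_min = 12, stem_max = 12,
                                             max_mismatches = mm,
                                             max_bulge_per_arm = 0))
    paste(ann$seq_id, ann$loop_start, ann$loop_end)
  }
  sets <- lapply(0:5, loops_at)
  for (i in 1:5) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  # The longest reported stem never shrinks when constraints are relaxed.
  max_stem <- function(params) {
    ann <- find_stem_loops(x, params)
    if (nrow(ann) == 0) 0L else max(ann$stem_length)
  }
  expect_lte(max_stem(hairpin_params(max_mismatches = 2)),
             max_stem(hairpin_params(max_mismatches = 5)))
  expect_lte(max_stem(hairpin_params(stem_min = 12, stem_max = 16)),
             max_stem(hairpin_params(stem_min = 10, stem_max = 20)))
})

test_that("terminal windows clamp and selection honors containment and rank", {
  x200 <- seq_tbl("a", random_seq(200))
  w <- extract_terminal_window(x200, "three_prime", 50)
  expect_identical(w$length, 50L)
  expect_identical(w$seq, substr(x200$seq, 151, 200))
  expect_identical(w$offset, 150L)
  w5 <- extract_terminal_window(x200, "five_prime", 50)
  expect_identical(w5$seq, substr(x200$seq, 1, 50))
  x30 <- seq_tbl("b", random_seq(30))
  expect_identical(extract_terminal_window(x30, "three_prime", 50)$length, 30L)

  # GC-only hairpin in an A-only background: annotations stay inside the
  # hairpin span, so containment decides selection.
  hp <- hairpin_str("GGCGCCGGCGGC", "AACAA")
  g60 <- seq_tbl("g", paste0(strrep("A", 10), hp, strrep("A", 21)))
  expect_identical(
    nrow(select_terminal_stemloops(g60, find_stem_loops(g60), window = 50)), 1L)
  h100 <- seq_tbl("h", paste0(hp, strrep("A", 71)))
  expect_identical(
    nrow(select_terminal_stemloops(h100, find_stem_loops(h100), window = 50)), 0L)
  expect_identical(
    nrow(select_terminal_stemloops(h100, find_stem_loops(h100),
                                   end = "five_prime", window = 50)), 1L)

  # Ranking: with two clean hairpins (stems 14 and 11) the longer stem wins.
  two <- seq_tbl("two", paste0(hairpin_str("GTCAGTGACTGGAC", "CCCAA"), "AA",
                               hairpin_str("TGGACTTGACT", "CACAA")))
  p0 <- hairpin_params(max_mismatches = 0)
  sel <- select_terminal_stemloops(two, find_stem_loops(two, p0),
                                   window = 62, params = p0)
  expect_identical(sel$stem_length, 14L)

  # A window too small for any hairpin warns and returns nothing.
  expect_warning(
    none <- select_terminal_stemloops(g60, find_stem_loops(g60), window = 20),
    "minimal hairpin span")
  expect_identical(nrow(none), 0L)
})

test_that("terminal selection matches an independent ranking oracle", {
  withr::local_seed(87)
  for (i in 1:12) {
    x <- seq_tbl("r", random_seq(80))
    ann <- find_stem_loops(x)
    for (end in c("three_prime", "five_prime")) {
      got <- select_terminal_stemloops(x, ann, end = end, window = 50)
      want <- rank_terminal_oracle(as.data.frame(ann), x$length, end, 50)
      expect_identical(nrow(got), nrow(want))
      if (nrow(got) == 1) {
        expect_identical(as.data.frame(got), as.data.frame(want),
                         ignore_attr = TRUE)
      }
    }
  }
})
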