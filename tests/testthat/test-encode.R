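test_that("k-mer frequencies match a naive counting oracle", {
  k4 <- kmer_frequencies(seq_tbl("x", "AAAA"))
  expect_identical(attr(k4, "scheme"), "sequence_kmer")
  expect_identical(ncol(k4), 81L)  # id + 16 + 64
  expect_identical(k4$AA, 1)
  expect_identical(k4$AAA, 1)
  expect_identical(sum(as.matrix(k4[, -1])), 2)
  ka <- kmer_frequencies(seq_tbl("x", "ACGT"))
  expect_identical(unname(unlist(ka[, c("AC", "CG", "GT")])), rep(1 / 3, 3))
  expect_identical(unname(unlist(ka[, c("ACG", "CGT")])), rep(1 / 2, 2))

  withr::local_seed(8)
  for (s in c(vapply(1:8, function(i) random_seq(50), character(1)),
              vapply(1:4, function(i) random_seq(30, c(BASES, "N")),
                     character(1)))) {
    got <- kmer_frequencies(seq_tbl("r", s))
    for (k in 2:3) {
      want <- naive_kmer_freq(s, k)
      expect_equal(unlist(got[, names(want)]), want, ignore_attr = TRUE)
    }
  }
  # Normalization identity: without N each width block sums to one.
  clean <- kmer_frequencies(seq_tbl("c", random_seq(50)))
  expect_equal(sum(clean[, 2:17]), 1)
  expect_equal(sum(clean[, 18:81]), 1)
  expect_warning(short <- kmer_frequencies(seq_tbl("s", "AC")),
                 "shorter than 3")
  expect_identical(sum(as.matrix(short[, 18:81])), 0)
})

test_that("loop encoding is positionwise one-hot over the first five bases", {
  b <- encode_loop("GGATA")  # DNA spelling of the eel LINE loop GGAUA
  expect_identical(ncol(b), 20L)
  expect_identical(colnames(b)[1:4], c("LP0:A", "LP0:C", "LP0:G", "LP0:T"))
  hot <- colnames(b)[b[1, ] == 1]
  expect_identical(hot, c("LP0:G", "LP1:G", "LP2:A", "LP3:T", "LP4:A"))
  long <- encode_loop("AAAAAAA")  # only the first five positions count
  expect_identical(colnames(long)[long[1, ] == 1],
                   paste0("LP", 0:4, ":A"))
  withr::local_seed(2)
  for (i in 1:5) expect_identical(sum(encode_loop(random_seq(7))), 5)
  expect_identical(sum(encode_loop("GNATA")[1, 5:8]), 0)  # N quartet zero
  expect_error(encode_loop("GGA"), "shorter than 5")
})

test_that("bulge encoding fills loop-proximal slots and zero-pads", {
  expect_identical(sum(encode_bulge("", "")), 0)
  b <- encode_bulge("AG", "")
  expect_identical(colnames(b)[b[1, ] == 1], c("LB0:A", "LB1:G"))
  expect_identical(sum(encode_bulge("ACT", "GGG")), 6)
  g <- encode_bulge("", "GGG")
  expect_identical(colnames(g)[g[1, ] == 1],
                   c("RB0:G", "RB1:G", "RB2:G"))
  expect_error(encode_bulge("ACTG", ""), "longer than 3")
})

test_that("stem encoding looks up dinucleotide properties step-major", {
  tab <- dinuc_property_table()
  gg <- encode_stem("GGGGGGGGGG", tab)
  expect_identical(ncol(gg), 90L)
  expect_identical(colnames(gg)[1:2], c("LS0:shift", "LS0:slide"))
  expect_lte(length(unique(as.numeric(gg))), 10L)
  ggrow <- as.numeric(as.matrix(tab[tab$dinucleotide == "GG", -1]))
  for (s in 0:8) {
    expect_identical(as.numeric(gg[1, (10 * s + 1):(10 * s + 10)]), ggrow)
  }
  # Alternating arm: loop-adjacent step is GC, then CG, alternating outward.
  alt <- encode_stem("GCGCGCGCGC", tab)
  gcrow <- as.numeric(as.matrix(tab[tab$dinucleotide == "GC", -1]))
  cgrow <- as.numeric(as.matrix(tab[tab$dinucleotide == "CG", -1]))
  for (s in 0:8) {
    want <- if (s %% 2 == 0) gcrow else cgrow
    expect_identical(as.numeric(alt[1, (10 * s + 1):(10 * s + 10)]), want)
  }
  # Only the ten loop-proximal bases are read.
  expect_identical(encode_stem("AAAAAGCGCGCGCGC", tab),
                   encode_stem("GCGCGCGCGC", tab))
  expect_warning(nn <- encode_stem("GGGGNGGGGG", tab), "contained N")
  expect_identical(sum(nn == 0), 20L)  # steps LS4 and LS5 zeroed
  expect_error(encode_stem("GGGGG", tab), "shorter than 10")
})

test_that("structure vectors satisfy the 90 + 20 + 24 = 134 contract", {
  x <- seq_tbl("hp", paste0(strrep("A", 10), hairpin_str("GGCGCCGGCGGC", "GGATA"),
                            strrep("A", 21)))
  sl <- select_terminal_stemloops(x, find_stem_loops(x), window = 50)
  fv <- encode_structure(sl)
  expect_identical(attr(fv, "scheme"), "structure_sl")
  expect_identical(setdiff(names(fv), "id"), structure_feature_names())
  expect_identical(length(structure_feature_names()), 134L)
  expect_identical(sum(as.matrix(fv[, 92:111])), 5)   # loop one-hot block
  expect_identical(sum(as.matrix(fv[, 112:135])), 0)  # no bulges -> zeros
  expect_identical(encode_structure(sl), fv)          # deterministic
  # Ineligible hairpins are refused, and the filter removes them.
  short_loop <- seq_tbl("sl", hairpin_str("GGCGCCGGCGGC", "CACA"))
  ann <- select_terminal_stemloops(short_loop, find_stem_loops(short_loop),
                                   window = 50)
  expect_identical(ann$loop_end - ann$loop_start, 4L)
  expect_error(encode_structure(ann), "not eligible")
  expect_identical(nrow(eligible_stemloops(ann)), 0L)
})

test_that("the bundled property table is complete, finite and RNA-keyed", {
  tab <- dinuc_property_table()
  expect_identical(nrow(tab), 16L)
  expect_identical(ncol(tab), 11L)
  expect_true(all(is.finite(as.matrix(tab[, -1]))))
  expect_setequal(tab$dinucleotide,
                  as.vector(outer(c("A", "C", "G", "U"),
                                  c("A", "C", "G", "U"), paste0)))
  # Thermodynamic symmetry: each step equals its reverse complement.
  rc <- function(d) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  for (d in tab$dinucleotide) {
    expect_identical(tab$free_energy[tab$dinucleotide == d],
                     tab$free_energy[tab$dinucleotide == rc(d)])
    expect_identical(tab$enthalpy[tab$dinucleotide == d],
                     tab$enthalpy[tab$dinucleotide == rc(d)])
  }
  expect_error(stemloopr:::validate_property_table(tab[-1, ]), "16")
})
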