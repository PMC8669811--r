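test_that("AAC computes per-residue frequencies in fixed A..Y order", {
  f <- encode_aac(peptide_tbl("AAAAC", "ACDEFGHIKLMNPQRSTVWY", "GG"))
  expect_equal(feature_names(f), paste0("AAC:", AA20))
  m <- feature_matrix(f)
  expect_equal(unname(m[1, c("AAC:A", "AAC:C")]), c(0.8, 0.2))
  expect_equal(sum(m[1, ] != 0), 2)
  expect_equal(unname(m[2, ]), rep(0.05, 20))
  expect_equal(unname(m[3, "AAC:G"]), 1)
})

test_that("AAC and GDC rows are non-negative and sum to one", {
  p <- random_peptides(25, seed = 3)
  for (f in list(encode_aac(p), encode_gdc(p, 1), encode_gdc(p, 4))) {
    m <- feature_matrix(f)
    expect_true(all(m >= 0))
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)))
  }
})

test_that("GDC counts position pairs (i, i + g), giving L - g pairs", {
  g1 <- feature_matrix(encode_gdc(peptide_tbl("AAC"), 1))
  expect_equal(unname(g1[1, c("GDC1:AA", "GDC1:AC")]), c(0.5, 0.5))
  g2 <- feature_matrix(encode_gdc(peptide_tbl("ACDE"), 2))
  expect_equal(unname(g2[1, c("GDC2:AD", "GDC2:CE")]), c(0.5, 0.5))
  g4 <- feature_matrix(encode_gdc(peptide_tbl("ACDEF"), 4))
  expect_equal(unname(g4[1, "GDC4:AF"]), 1)
  expect_equal(sum(g4[1, ] != 0), 1)
})

test_that("GDC rejects sequences with no g-gap pair, naming the record", {
  expect_error(encode_gdc(peptide_tbl("ACDE"), 4), "P1")
  expect_error(encode_gdc(peptide_tbl("ACDEF", "ACD"), 3), "P2")
  expect_error(encode_gdc(peptide_tbl("ACDEF"), 5), "g must be")
})

test_that("GDC matches a brute-force pair enumerator on random sequences", {
  p <- random_peptides(12, len_range = c(6, 12), seed = 17)
  for (g in 1:4) {
    m <- feature_matrix(encode_gdc(p, g))
    for (r in seq_len(nrow(p))) {
      expected <- oracle_gap_pairs(p$sequence[r], g)
      expect_equal(unname(m[r, ]), unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("DDE matches the per-dipeptide formula oracle", {
  p <- peptide_tbl("AAAAA", "ACDEF", random_peptides(3, seed = 5)$sequence)
  m <- feature_matrix(encode_dde(p))
  for (r in seq_len(nrow(p))) {
    expect_equal(unname(m[r, ]), unname(oracle_dde(p$sequence[r])),
                 tolerance = 1e-10)
  }
})

test_that("DDE of a single-dipeptide homopolymer follows the closed form", {
  # "AAAAA": DC(AA) = 1, TM(AA) = (4/61)^2, TV = TM(1-TM)/4
  tm <- (4 / 61)^2
  expected <- (1 - tm) / sqrt(tm * (1 - tm) / 4)
  m <- feature_matrix(encode_dde(peptide_tbl("AAAAA")))
  expect_equal(unname(m[1, "DDE:AA"]), expected, tolerance = 1e-12)
  # absent dipeptides deviate below their theoretical mean
  expect_true(all(m[1, colnames(m) != "DDE:AA"] < 0))
})

test_that("DDE depends on the sequence only through dipeptide counts and L", {
  p <- peptide_tbl("ACACA", "ACACA")
  m <- feature_matrix(encode_dde(p))
  expect_identical(m[1, ], m[2, ])
  expect_error(encode_dde(peptide_tbl("A")), "length")
})

test_that("a custom codon table changes the theoretical mean accordingly", {
  uniform <- codon_table(setNames(rep(3, 20), AA20))
  expect_equal(uniform$cn, 60)
  m <- feature_matrix(encode_dde(peptide_tbl("ACDEF"), uniform))
  tm <- (3 / 60)^2
  tv <- tm * (1 - tm) / 4
  expect_equal(unname(m[1, "DDE:AC"]), (0.25 - tm) / sqrt(tv),
               tolerance = 1e-12)
})

test_that("combine concatenates blocks with prefixed names in order", {
  p <- validate_peptides(random_peptides(3, seed = 9))
  p$label <- c(1L, 0L, 1L)
  aac <- encode_aac(p)
  dde <- encode_dde(p)
  gdc1 <- encode_gdc(p, 1)
  both <- combine_features(aac, dde)
  expect_equal(length(feature_names(both)), 420)
  expect_equal(feature_names(both), c(feature_names(aac), feature_names(dde)))
  expect_equal(both$label, p$label)
  expect_identical(combine_features(aac), aac)
  all3 <- combine_features(aac, dde, gdc1)
  expect_equal(length(feature_names(all3)), 820)
  shuffled <- dde[c(2, 1, 3), ]
  expect_error(combine_features(aac, shuffled), "sample")
})

test_that("encode_peptides validates encoder names", {
  p <- random_peptides(2, seed = 1)
  expect_error(encode_peptides(p, c("aac", "bogus")), "unknown encoder")
  f <- encode_peptides(p, c("gdc2", "aac"))
  expect_equal(length(feature_names(f)), 420)
  expect_true(startsWith(feature_names(f)[1], "GDC2:"))
})

test_that("encoders are deterministic and empty input is an error", {
  p <- random_peptides(5, seed = 21)
  expect_identical(encode_dde(p), encode_dde(p))
  expect_identical(encode_gdc(p, 2), encode_gdc(p, 2))
  empty <- tibble::tibble(id = character(), sequence = character())
  expect_error(encode_aac(empty), "empty")
})

test_that("feature TSV round-trips losslessly with labels", {
  p <- validate_peptides(random_peptides(4, seed = 2))
  p$label <- c(0L, 1L, 0L, 1L)
  f <- encode_peptides(p, c("aac", "dde"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features(f, tsv)
  back <- read_features(tsv)
  expect_equal(back$label, f$label)
  expect_equal(feature_matrix(back), feature_matrix(f), tolerance = 1e-15)
})
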