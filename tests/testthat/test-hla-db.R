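write_fa <- function(lines) {
  fa <- tempfile(fileext = ".fa")
  writeLines(lines, fa)
  fa
}

test_that("IMGT-dialect FASTA parses into allele records", {
  fa <- write_fa(c(
    ">HLA:HLA00001 A*01:01:01:01 24 bp",
    "acgtacgtacgtacgtacgtacgt",
    ">HLA:HLA00002 A*02:01 20 bp",
    "ACGTACGTACGTACGTACGT"
  ))
  al <- read_imgt_fasta(fa)
  expect_equal(nrow(al), 2L)
  expect_equal(al$accession, c("HLA:HLA00001", "HLA:HLA00002"))
  expect_equal(al$allele, c("A*01:01:01:01", "A*02:01"))
  expect_equal(al$locus, c("A", "A"))
  expect_equal(al$sequence[1], strrep("ACGT", 6))  # uppercased
  expect_equal(al$length, c(24L, 20L))
  expect_equal(al$stated_length, c(24L, 20L))
  expect_true(all(al$source == "observed"))
})

test_that("header and length violations are reported precisely", {
  fa <- write_fa(c(">HLA:HLA00001 A*01:01 10 bp", "ACGTACGTACGTACGT"))
  expect_error(read_imgt_fasta(fa), "stated length")

  fa2 <- write_fa(c(">HLA:HLA00001 A*01:01 12 bp", "ACGTACGTACGT",
                    ">justaname", "ACGTACGTACGT"))
  expect_error(read_imgt_fasta(fa2), "line 3")

  # the plain dialect accepts bare names
  al <- read_imgt_fasta(write_fa(c(">A*01:01", "ACGTACGTACGT")),
                        dialect = "plain")
  expect_equal(al$allele, "A*01:01")
  expect_true(is.na(al$accession))
})

test_that("empty FASTA yields an empty allele table, not an error", {
  fa <- tempfile(fileext = ".fa")
  file.create(fa)
  al <- read_imgt_fasta(fa)
  expect_equal(nrow(al), 0L)
})

test_that("completeness defaults to the locus-wise length rule", {
  fa <- write_fa(c(
    ">HLA:1 B*07:02 30 bp", strrep("ACGTA", 6),
    ">HLA:2 B*08:01 20 bp", strrep("ACGTA", 4),   # 20 < 0.9 * 30
    ">HLA:3 B*15:01 28 bp", strrep("ACGTACG", 4)  # 28 >= 27
  ))
  al <- read_imgt_fasta(fa)
  expect_equal(al$is_complete, c(TRUE, FALSE, TRUE))
})

test_that("IMGT write/read round-trips records", {
  set.seed(42)
  al <- dplyr::bind_rows(allele_row("A*01:01", random_dna(150)),
                         allele_row("A*02:01", random_dna(140)))
  fa <- tempfile(fileext = ".fa")
  write_imgt_fasta(al, fa)
  back <- read_imgt_fasta(fa)
  expect_equal(back$allele, al$allele)
  expect_equal(back$sequence, al$sequence)
})

test_that("supplemented reference replaces HLA transcripts by the diversity", {
  set.seed(7)
  tx <- reference_set(
    c("T1", "T2", "T3", "HLA_T1", "HLA_T2"),
    replicate(5, random_dna(120)),
    is_hla = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    locus = c(NA, NA, NA, "A", "B")
  )
  al <- dplyr::bind_rows(lapply(sprintf("A*%02d:01", 1:6), function(n) {
    allele_row(n, random_dna(100))
  }))
  sup <- build_supplemented_reference(tx, c("HLA_T1", "HLA_T2"), al)
  expect_equal(nrow(sup), 5 - 2 + 6)
  # non-HLA sequences carried over byte-identically
  kept <- sup[!sup$is_hla, ]
  expect_equal(kept$sequence[match(c("T1", "T2", "T3"), kept$id)],
               tx$sequence[1:3])
  expect_true(all(sup$is_hla[sup$id %in% al$allele]))
  expect_equal(sup$locus[sup$id == "A*01:01"], "A")

  # degenerate: no alleles
  none <- build_supplemented_reference(tx, c("HLA_T1", "HLA_T2"),
                                       al[integer(0), ])
  expect_equal(none$id, c("T1", "T2", "T3"))

  # errors
  expect_error(build_supplemented_reference(tx, "NOPE", al), "NOPE")
  dup <- dplyr::bind_rows(al, al[1, ])
  expect_error(build_supplemented_reference(tx, c("HLA_T1", "HLA_T2"), dup),
               "duplicated")
})

test_that("divergence is normalized edit distance with strict N handling", {
  expect_equal(divergence("ACGT", "ACGT"), 0)
  expect_equal(divergence("ACGT", "ACGA"), 0.25)
  expect_equal(divergence("AC", "A"), 0.5)  # edit distance 1 / max length 2
  expect_error(divergence("", "ACGT"), "empty")
  # N never matches, not even another N
  expect_equal(divergence("N", "N"), 1)
  expect_equal(divergence("AN", "AN"), 0.5)
})

test_that("divergence agrees with a DP oracle and is symmetric", {
  set.seed(11)
  for (i in 1:40) {
    a <- random_dna(sample(1:50, 1))
    b <- random_dna(sample(1:50, 1))
    expect_equal(divergence(a, b), dp_edit_distance(a, b) / max(nchar(a),
                                                                nchar(b)))
    expect_identical(divergence(a, b), divergence(b, a))
  }
})

test_that("partial alleles are completed from the closest full sequence", {
  set.seed(3)
  c1 <- random_dna(300)
  c2 <- random_dna(300)
  cands <- dplyr::bind_rows(allele_row("A*02:01", c1),
                            allele_row("A*03:01", c2))
  # partial exactly matches an interior region of candidate 1 only
  partial <- allele_row("A*01:01", substr(c1, 101, 200), is_complete = FALSE)
  done <- complete_partial_sequence(partial, cands)
  expect_equal(done$sequence, c1)  # region substituted verbatim == candidate
  expect_equal(done$source, "imputed_flanks")
  expect_true(done$is_complete)
  expect_equal(done$closest_complete, "A*02:01")

  # equal-distance tie resolves to the smallest allele name
  shared <- random_dna(80)
  tied <- dplyr::bind_rows(
    allele_row("A*05:01", paste0(random_dna(50), shared, random_dna(50))),
    allele_row("A*04:01", paste0(random_dna(60), shared, random_dna(40))))
  p2 <- allele_row("A*01:02", shared, is_complete = FALSE)
  expect_equal(complete_partial_sequence(p2, tied)$closest_complete,
               "A*04:01")

  # hybrid length bounded by candidate lengths for substitution-only partials
  expect_true(nchar(complete_partial_sequence(p2, tied)$sequence) %in%
                nchar(tied$sequence))

  expect_error(complete_partial_sequence(partial, cands[integer(0), ]),
               "no complete candidate")
  # a region with no resemblance to any candidate is rejected
  far <- allele_row("A*09:09", strrep("A", 100), is_complete = FALSE)
  only_c <- allele_row("A*02:09", strrep("C", 300))
  expect_error(complete_partial_sequence(far, only_c), "not locatable")
})

test_that("complete_all leaves complete records alone and imputes the rest", {
  set.seed(4)
  full <- random_dna(200)
  al <- dplyr::bind_rows(
    allele_row("B*07:01", full),
    allele_row("B*08:01", substr(full, 51, 150), is_complete = FALSE))
  out <- complete_all(al)
  expect_true(all(out$is_complete))
  expect_equal(out$source, c("observed", "imputed_flanks"))
  expect_equal(out$sequence[2], full)
})

test_that("reference sets validate ids and locus flags", {
  expect_error(reference_set(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(reference_set("a", "ACGT", is_hla = TRUE), "locus")
  expect_error(reference_set("a", "ACGT", is_hla = FALSE, locus = "A"),
               "locus NA")
  rs <- reference_set(c("a", "b"), c("ACGT", "AAAA"),
                      is_hla = c(TRUE, FALSE), locus = c("A", NA))
  fa <- tempfile(fileext = ".fa")
  write_reference_set(rs, fa)
  back <- read_reference_set(fa)
  expect_equal(back$id, rs$id)
  expect_equal(back$sequence, rs$sequence)
  expect_equal(back$is_hla, rs$is_hla)
  expect_equal(back$locus, rs$locus)
})
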