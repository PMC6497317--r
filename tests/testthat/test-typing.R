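ab_tbl <- function(...) {
  x <- c(...)
  tibble::tibble(ref_id = names(x), est_count = as.numeric(x))
}

test_that("candidate selection applies the intra-lineage threshold", {
  # A*01:02 has 20/110 ~ 0.18 of its lineage: dropped
  got <- top_candidates(ab_tbl("A*01:01" = 90, "A*01:02" = 20))
  expect_equal(got, "A*01:01")

  # a single expressed allele is always kept (lineage fraction 1)
  expect_equal(top_candidates(ab_tbl("A*03:01" = 4)), "A*03:01")

  # exactly 25% of the lineage is kept (threshold inclusive)
  got <- top_candidates(ab_tbl("A*01:01" = 75, "A*01:02" = 25))
  expect_setequal(got, c("A*01:01", "A*01:02"))

  # at most n alleles considered, ranked by count
  many <- ab_tbl("A*01:01" = 60, "A*02:01" = 50, "A*03:01" = 40,
                 "A*04:01" = 30, "A*05:01" = 20, "A*06:01" = 10)
  expect_length(top_candidates(many, n = 5), 5)
  expect_false("A*06:01" %in% top_candidates(many, n = 5))

  # zero-count alleles are never candidates
  expect_equal(top_candidates(ab_tbl("A*01:01" = 0, "A*02:01" = 5)),
               "A*02:01")
  expect_length(top_candidates(ab_tbl("A*01:01" = 0)), 0)
})

test_that("zygosity calling follows the lineage and allele thresholds", {
  # two lineages, second at 70/150 >= 0.15: lineage-level heterozygote
  call <- call_genotype(ab_tbl("A*01:01" = 80, "A*02:01" = 70))
  expect_false(call$homozygous)
  expect_true(call$lineage_heterozygous)
  expect_equal(call$alleles, c("A*01:01", "A*02:01"))

  # one lineage, second allele 5/100 < 0.15: provisional homozygote
  call <- call_genotype(ab_tbl("A*01:01" = 95, "A*01:02" = 5))
  expect_true(call$homozygous)
  expect_true(call$confirmed)
  expect_equal(call$alleles, "A*01:01")

  # single allele: homozygote
  call <- call_genotype(ab_tbl("A*01:01" = 100))
  expect_true(call$homozygous)

  # one lineage, second allele 20/100 >= 0.15: allele-level heterozygote
  call <- call_genotype(ab_tbl("A*01:01" = 80, "A*01:02" = 20))
  expect_false(call$homozygous)
  expect_false(call$lineage_heterozygous)
  expect_equal(call$alleles, c("A*01:01", "A*01:02"))

  # thresholds are inclusive at exactly 0.15
  call <- call_genotype(ab_tbl("A*01:01" = 85, "A*02:01" = 15))
  expect_false(call$homozygous)
  call <- call_genotype(ab_tbl("A*01:01" = 85, "A*01:02" = 15))
  expect_false(call$homozygous)

  expect_error(call_genotype(ab_tbl("A*01:01" = 0)), "no call")
})

test_that("heterozygote confirmation collapses indistinguishable alleles", {
  set.seed(16)
  base <- random_dna(400)
  # second allele differs at 8 consecutive positions (complemented bases)
  variant <- paste0(substr(base, 1, 199),
                    chartr("ACGT", "TGCA", substr(base, 200, 207)),
                    substr(base, 208, 400))
  refs <- reference_set(c("A*01:01", "A*01:02"), c(base, variant),
                        is_hla = TRUE, locus = c("A", "A"))
  idx <- build_kmer_index(refs, k = 15)
  # reads: 30 from shared prefix (compatible with both), 10 covering the
  # variant (unique to A*01:02)
  shared_reads <- vapply(1:30, function(i) substr(base, i, i + 49),
                         character(1))
  var_reads <- vapply(175:184, function(i) substr(variant, i, i + 49),
                      character(1))
  reads <- c(shared_reads, var_reads)
  aln <- pseudoalign(idx, reads)
  seqs <- stats::setNames(refs$sequence, refs$id)

  call <- new_genotype_call("A", c("A*01:01", "A*01:02"), FALSE, FALSE, FALSE)
  confirmed <- confirm_heterozygote(call, aln, reads, sequences = seqs,
                                    locus_total = 40, k = 15)
  expect_false(confirmed$homozygous)
  expect_true(confirmed$confirmed)
  expect_gte(confirmed$diagnostics[["confirm_fraction"]], 0.01)

  # identical sequences: every read compatible with the lead is removed,
  # nothing supports the second allele -> homozygote
  twins <- reference_set(c("A*01:01", "A*01:03"), c(base, base),
                         is_hla = TRUE, locus = c("A", "A"))
  idx2 <- build_kmer_index(twins, k = 15)
  aln2 <- pseudoalign(idx2, shared_reads)
  call2 <- new_genotype_call("A", c("A*01:01", "A*01:03"), FALSE, FALSE, FALSE)
  confirmed2 <- confirm_heterozygote(call2, aln2, shared_reads,
                                     sequences = stats::setNames(
                                       twins$sequence, twins$id),
                                     locus_total = 30, k = 15)
  expect_true(confirmed2$homozygous)
  expect_equal(confirmed2$alleles, "A*01:01")

  # homozygous input passes through untouched
  hom <- new_genotype_call("A", "A*01:01", TRUE, FALSE, TRUE)
  expect_identical(confirm_heterozygote(hom, aln, reads, sequences = seqs,
                                        locus_total = 40), hom)
})

test_that("end-to-end typing recovers error-free genotypes exactly", {
  p <- make_synthetic_panel(n_loci = 2, alleles_per_locus = 6,
                            divergence_grid = c(0, 0.03, 0.06),
                            root_length = 800, seed = 17)
  bg <- make_background_transcripts(2, length = 800, seed = 18)
  rs <- panel_reference_sets(p, bg)
  g <- sample_genotypes(p, 2, het_fraction = 0.7, seed = 19)
  seqs <- stats::setNames(c(p$alleles$sequence, bg$sequence),
                          c(p$alleles$allele, bg$id))
  idx <- build_kmer_index(rs$supplemented)
  calls_tbl <- dplyr::bind_rows(lapply(unique(g$sample), function(s) {
    sim <- simulate_sample(g[g$sample == s, ], bg, seqs, n_fragments = 15000,
                           seed = 20 + match(s, unique(g$sample)),
                           error_rate = 0)
    genotype_table(genotype_sample(sim$reads1, sim$reads2, rs$supplemented,
                                   index = idx), sample = s)
  }))
  # full-resolution concordance: every allele recovered
  expect_equal(typing_concordance(calls_tbl, g, resolution_fields = 4L), 1,
               ignore_attr = TRUE)
})

test_that("a locus without reads is a no-call and leaves others intact", {
  p <- make_synthetic_panel(n_loci = 2, alleles_per_locus = 4,
                            divergence_grid = c(0, 0.05), root_length = 600,
                            paralog_loci = NULL, seed = 23)
  bg <- make_background_transcripts(1, length = 600, seed = 24)
  rs <- panel_reference_sets(p, bg)
  seqs <- stats::setNames(c(p$alleles$sequence, bg$sequence),
                          c(p$alleles$allele, bg$id))
  # only locus L1 expressed
  counts <- tibble::tibble(id = c("L1*01:01", "L1*02:01", bg$id),
                           count = c(2000, 2000, 1000))
  set.seed(25)
  reads <- simulate_reads(counts, seqs, error_rate = 0)
  calls <- genotype_sample(reads$reads1, reads$reads2, rs$supplemented)
  expect_length(calls[["L2"]]$alleles, 0)
  expect_setequal(calls[["L1"]]$alleles, c("L1*01:01", "L1*02:01"))

  expect_error(genotype_sample(character(0), NULL, rs$supplemented),
               "empty fragment stream")
})

test_that("heterozygotes with few distinguishing sites are never collapsed", {
  # sibling alleles differ by 8 substitutions; at default thresholds a
  # simulated heterozygote must not be called homozygous
  for (seed in c(31, 32)) {
    p <- make_synthetic_panel(n_loci = 1, alleles_per_locus = 2,
                              divergence_grid = 0, root_length = 800,
                              paralog_loci = NULL, seed = seed)
    bg <- make_background_transcripts(1, length = 800, seed = seed + 50)
    rs <- panel_reference_sets(p, bg)
    seqs <- stats::setNames(c(p$alleles$sequence, bg$sequence),
                            c(p$alleles$allele, bg$id))
    g <- tibble::tibble(sample = "S01", locus = "L1", allele1 = "L1*01:01",
                        allele2 = "L1*01:02", heterozygous = TRUE)
    sim <- simulate_sample(g, bg, seqs, n_fragments = 8000, seed = seed + 100)
    calls <- genotype_sample(sim$reads1, sim$reads2, rs$supplemented)
    expect_false(calls[["L1"]]$homozygous)
    expect_setequal(calls[["L1"]]$alleles, c("L1*01:01", "L1*01:02"))
  }
})

test_that("concordance compares truncated names with best matching", {
  truth <- tibble::tibble(sample = "s", locus = "A",
                          allele1 = "A*01:01:02", allele2 = "A*02:01")
  calls <- tibble::tibble(sample = "s", locus = "A",
                          allele1 = "A*01:01:01:01", allele2 = "A*02:01",
                          homozygous = FALSE)
  # third/fourth fields differ but two-field truncation agrees
  expect_equal(typing_concordance(calls, truth, 2), 1, ignore_attr = TRUE)
  expect_equal(typing_concordance(calls, truth, 3), 0.5, ignore_attr = TRUE)

  # order of alleles is irrelevant (bipartite matching)
  swapped <- calls
  swapped$allele1 <- "A*02:01"; swapped$allele2 <- "A*01:01"
  expect_equal(typing_concordance(swapped, truth, 2), 1, ignore_attr = TRUE)

  # one of two alleles wrong scores 0.5; missing locus scores 0
  wrong <- calls; wrong$allele2 <- "A*03:01"
  expect_equal(typing_concordance(wrong, truth, 2), 0.5, ignore_attr = TRUE)
  none <- calls[integer(0), ]
  expect_equal(suppressMessages(typing_concordance(none, truth, 2)), 0,
               ignore_attr = TRUE)

  # homozygous call against heterozygous truth matches one copy
  hom <- tibble::tibble(sample = "s", locus = "A", allele1 = "A*01:01",
                        allele2 = NA_character_, homozygous = TRUE)
  expect_equal(typing_concordance(hom, truth, 2), 0.5, ignore_attr = TRUE)
})
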