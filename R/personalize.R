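#' Build the personalized reference for quantification
#'
#' Replaces all HLA records of the supplemented reference by exactly the
#' alleles called for the individual: one record per homozygous locus, two
#' per heterozygous locus. Non-HLA transcripts are untouched. No-call loci
#' contribute no records (logged).
#'
#' @param genotypes A `genotype_calls` list from [genotype_sample()] (or any
#'   list of `genotype_call` objects).
#' @param supplemented The supplemented [reference_set()]; every called
#'   allele must be present in it.
#' @return A personalized `reference_set`.
#' @export
build_personalized_index <- function(genotypes, supplemented) {
  supplemented <- validate_reference_set(supplemented)
  wanted <- unique(unlist(lapply(genotypes, function(g) g$alleles)))
  missing <- setdiff(wanted, supplemented$id[supplemented$is_hla])
  if (length(missing) > 0) {
    stop("called allele(s) missing from the supplemented reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  no_calls <- names(genotypes)[vapply(genotypes,
                                      function(g) length(g$alleles) == 0,
                                      logical(1))]
  if (length(no_calls) > 0) {
    message("no-call loci carry no personalized reference: ",
            paste(no_calls, collapse = ", "))
  }
  keep <- !supplemented$is_hla | supplemented$id %in% wanted
  validate_reference_set(supplemented[keep, ])
}

#' Quantify a sample against a reference set
#'
#' Builds the k-mer index, pseudoaligns the fragments, and runs the EM. TPM
#' is computed over the whole reference set (HLA and non-HLA records), i.e.
#' on the whole-transcriptome scale.
#'
#' @param refs A [reference_set()] (typically personalized).
#' @param reads1,reads2 Fragment mate sequences.
#' @param k K-mer size.
#' @param mean_fragment Mean fragment length for effective lengths.
#' @param tol,max_iter EM parameters.
#' @return Abundance tibble ([em_quantify()]) with an added `locus` column
#'   (`NA` for non-HLA records) plus attributes `n_unmapped`, `n_too_short`,
#'   `n_fragments`.
#' @export
quantify_sample <- function(refs, reads1, reads2 = NULL, k = 31L,
                            mean_fragment = 250, tol = 0.01,
                            max_iter = 1000L) {
  refs <- validate_reference_set(refs)
  index <- build_kmer_index(refs, k = k)
  aln <- pseudoalign(index, reads1, reads2)
  eff <- effective_length(index$ref_lengths, mean_fragment)
  ab <- em_quantify(aln$classes, eff, tol = tol, max_iter = max_iter)
  ab$locus <- unname(reference_locus_map(refs)[ab$ref_id])
  attr(ab, "n_unmapped") <- aln$n_unmapped
  attr(ab, "n_too_short") <- aln$n_too_short
  attr(ab, "n_fragments") <- aln$n_fragments
  ab
}

#' Allele-level expression table
#'
#' Restricts a personalized quantification to the HLA allele records and
#' annotates sample, locus, and lineage.
#'
#' @param abundances Output of [quantify_sample()] on a personalized index.
#' @param sample Sample identifier.
#' @return Tibble `sample`, `allele`, `locus`, `lineage`, `est_count`, `tpm`.
#' @export
allele_expression <- function(abundances, sample = "sample1") {
  hla <- abundances[!is.na(abundances$locus), ]
  tibble::tibble(
    sample = sample,
    allele = hla$ref_id,
    locus = hla$locus,
    lineage = allele_lineage(hla$ref_id),
    est_count = hla$est_count,
    tpm = hla$tpm
  )
}

#' Gene-level expression by summing allele estimates
#'
#' Summing the estimates of the (up to) two alleles carried at each locus
#' yields gene-level expression; a homozygous locus carries one reference
#' whose single estimate is the gene-level value.
#'
#' @param allele_expr An [allele_expression()] tibble.
#' @return Tibble `sample`, `locus`, `tpm`, `est_count`.
#' @export
gene_level <- function(allele_expr) {
  dplyr::summarise(
    dplyr::group_by(allele_expr, .data$sample, .data$locus),
    tpm = sum(.data$tpm), est_count = sum(.data$est_count),
    .groups = "drop")
}

#' Allele-specific expression of a heterozygous locus
#'
#' ASE is the proportion of the locus-level expression attributed to the
#' less expressed of the two alleles, so it lies in \[0, 0.5\] with 0.5 for
#' perfectly balanced expression. Undefined for homozygous loci and for loci
#' with zero total expression.
#'
#' @param tpm Numeric vector of exactly two allele TPM values (order
#'   irrelevant).
#' @return A proportion in \[0, 0.5\].
#' @examples
#' ase(c(30, 70))  # 0.3
#' @export
ase <- function(tpm) {
  if (length(tpm) != 2) {
    stop("ASE is defined only for heterozygous loci (exactly 2 alleles)",
         call. = FALSE)
  }
  if (sum(tpm) <= 0) stop("ASE undefined for zero total expression",
                          call. = FALSE)
  min(tpm) / sum(tpm)
}

#' ASE across all heterozygous loci of an expression table
#'
#' @param allele_expr An [allele_expression()] tibble (possibly row-bound
#'   over samples).
#' @return Tibble `sample`, `locus`, `ase` with one row per heterozygous
#'   locus with positive expression; homozygous or silent loci are skipped.
#' @export
ase_table <- function(allele_expr) {
  grp <- dplyr::group_by(allele_expr, .data$sample, .data$locus)
  counts <- dplyr::summarise(grp, n = dplyr::n(), total = sum(.data$tpm),
                             low = min(.data$tpm), .groups = "drop")
  het <- counts[counts$n == 2 & counts$total > 0, ]
  tibble::tibble(sample = het$sample, locus = het$locus,
                 ase = het$low / het$total)
}

#' Lineage-level expression
#'
#' Sums allele TPM within (sample, lineage); `filter_lineages()` keeps
#' lineages observed in at least `min_samples` samples, the usual restriction
#' before lineage-level contrasts.
#'
#' @param allele_expr An [allele_expression()] tibble.
#' @param lineage_expr Output of `lineage_expression()`.
#' @param min_samples Minimum number of distinct samples per lineage.
#' @return Tibble `sample`, `lineage`, `locus`, `tpm`.
#' @export
lineage_expression <- function(allele_expr) {
  dplyr::summarise(
    dplyr::group_by(allele_expr, .data$sample, .data$lineage, .data$locus),
    tpm = sum(.data$tpm), .groups = "drop")
}

#' @rdname lineage_expression
#' @export
filter_lineages <- function(lineage_expr, min_samples = 10L) {
  n_samples <- tapply(lineage_expr$sample, lineage_expr$lineage,
                      function(s) length(unique(s)))
  keep <- names(n_samples)[n_samples >= min_samples]
  lineage_expr[lineage_expr$lineage %in% keep, ]
}

#' Select the haplotype pair that best explains a multilocus genotype
#'
#' Exhaustive search over all unordered pairs of panel haplotypes for the
#' combination minimizing the total number of allele differences to the
#' genotype (per locus, the better of the two pairings of haplotype alleles
#' against genotype alleles). Ties are reported explicitly, and the returned
#' pair is the first in name order, so results are deterministic.
#'
#' @param genotype Named list (by locus) of length-2 character vectors of
#'   allele names.
#' @param panel Named list of haplotypes, each a named character vector
#'   locus -> allele, covering the genotype's loci.
#' @return List with `pair` (two haplotype names, sorted), `mismatches`
#'   (minimal total), and `ties` (tibble of all optimal pairs).
#' @export
infer_haplotype_pair <- function(genotype, panel) {
  if (length(panel) == 0) stop("empty haplotype panel", call. = FALSE)
  loci <- names(genotype)
  for (h in panel) {
    if (!all(loci %in% names(h))) {
      stop("panel haplotypes must cover the genotype's loci", call. = FALSE)
    }
  }
  hap_names <- sort(names(panel))
  pair_mismatch <- function(h1, h2) {
    sum(vapply(loci, function(l) {
      g <- genotype[[l]]
      a <- c(panel[[h1]][[l]], panel[[h2]][[l]])
      min((a[1] != g[1]) + (a[2] != g[2]), (a[1] != g[2]) + (a[2] != g[1]))
    }, numeric(1)))
  }
  combos <- expand.grid(i = seq_along(hap_names), j = seq_along(hap_names))
  combos <- combos[combos$i <= combos$j, ]
  mm <- mapply(function(i, j) pair_mismatch(hap_names[i], hap_names[j]),
               combos$i, combos$j)
  best <- min(mm)
  hits <- combos[mm == best, , drop = FALSE]
  ties <- tibble::tibble(hap1 = hap_names[hits$i], hap2 = hap_names[hits$j],
                         mismatches = best)
  ties <- ties[order(ties$hap1, ties$hap2), ]
  list(pair = c(ties$hap1[1], ties$hap2[1]), mismatches = best, ties = ties)
}

#' Write allele-expression and ASE tables
#'
#' @param x An [allele_expression()] or [ase_table()] tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
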