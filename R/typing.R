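#' Select candidate alleles at a locus
#'
#' From the full-diversity quantification, the top `n` expressed alleles of
#' the locus are taken, and an intra-lineage filter is applied: within the
#' selected set, an allele is kept only if it carries at least
#' `intra_lineage_threshold` (default 25%) of the summed expression of its
#' lineage. Alleles exactly at the threshold are kept. Ties on estimated
#' count are broken by allele name so candidate sets are deterministic.
#'
#' @param locus_abundances Abundance tibble ([em_quantify()] rows) for the
#'   alleles of a single locus; `ref_id` must be allele names.
#' @param n Number of top alleles to consider.
#' @param intra_lineage_threshold Minimum fraction of the lineage's summed
#'   expression (within the selected set) an allele must carry.
#' @return Character vector of candidate allele names, highest count first;
#'   empty for empty input.
#' @export
top_candidates <- function(locus_abundances, n = 5L,
                           intra_lineage_threshold = 0.25) {
  ab <- locus_abundances[locus_abundances$est_count > 0, ]
  if (nrow(ab) == 0) return(character(0))
  loci <- allele_locus(ab$ref_id)
  if (length(unique(loci)) > 1) {
    stop("top_candidates expects abundances of a single locus", call. = FALSE)
  }
  ab <- ab[order(-ab$est_count, ab$ref_id), ]
  ab <- utils::head(ab, n)
  lin <- allele_lineage(ab$ref_id)
  lin_sum <- tapply(ab$est_count, lin, sum)[lin]
  frac <- ab$est_count / as.numeric(lin_sum)
  ab$ref_id[frac >= intra_lineage_threshold - 1e-12]
}

new_genotype_call <- function(locus, alleles, homozygous, lineage_het,
                              confirmed, diagnostics = numeric(0)) {
  structure(list(locus = locus, alleles = alleles, homozygous = homozygous,
                 lineage_heterozygous = lineage_het, confirmed = confirmed,
                 diagnostics = diagnostics),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  g <- if (length(x$alleles) == 0) "no call"
       else paste(x$alleles, collapse = " / ")
  cat(x$locus, ": ", g,
      if (isTRUE(x$homozygous)) " (homozygous)" else "",
      if (isTRUE(x$confirmed)) " [confirmed]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Provisional genotype call from re-quantified candidates
#'
#' Given the candidate alleles of one locus re-quantified against the
#' per-individual candidate index, decides zygosity. With T the locus total:
#' if the second-ranked lineage carries at least `lineage_threshold * T`, the
#' individual is heterozygous at the lineage level and the lead allele of
#' each of the top two lineages composes the genotype. Otherwise, within the
#' single lead lineage, the second-ranked allele makes an allele-level
#' heterozygote when it reaches `zygosity_threshold * T`; otherwise the call
#' is a provisional homozygote for the lead allele. Both thresholds are
#' inclusive and expressed as fractions of the total locus read count.
#'
#' @param requant Abundance tibble of the locus's candidate alleles after
#'   re-quantification against the candidate index.
#' @param lineage_threshold Lineage-level heterozygosity threshold.
#' @param zygosity_threshold Allele-level heterozygosity threshold.
#' @return A `genotype_call`; heterozygous calls are provisional
#'   (`confirmed = FALSE`) until [confirm_heterozygote()], homozygous calls
#'   are final. Errors when the locus has no reads.
#' @export
call_genotype <- function(requant, lineage_threshold = 0.15,
                          zygosity_threshold = 0.15) {
  total <- sum(requant$est_count)
  if (nrow(requant) == 0 || total <= 0) {
    stop("no reads support this locus: no call", call. = FALSE)
  }
  locus <- unique(allele_locus(requant$ref_id))
  if (length(locus) > 1) {
    stop("call_genotype expects candidates of a single locus", call. = FALSE)
  }
  ab <- requant[order(-requant$est_count, requant$ref_id), ]
  lin <- allele_lineage(ab$ref_id)
  lin_sum <- tapply(ab$est_count, lin, sum)
  lin_rank <- names(lin_sum)[order(-as.numeric(lin_sum), names(lin_sum))]
  second_lin_frac <- if (length(lin_rank) >= 2) {
    as.numeric(lin_sum[lin_rank[2]]) / total
  } else 0
  eps <- 1e-12

  if (second_lin_frac >= lineage_threshold - eps) {
    leads <- vapply(lin_rank[1:2], function(l) ab$ref_id[lin == l][1],
                    character(1))
    leads <- leads[order(-ab$est_count[match(leads, ab$ref_id)], leads)]
    return(new_genotype_call(
      locus, unname(leads), homozygous = FALSE, lineage_het = TRUE,
      confirmed = FALSE,
      diagnostics = c(second_lineage_fraction = second_lin_frac)))
  }

  within <- ab[lin == lin_rank[1], ]
  second_allele_frac <- if (nrow(within) >= 2) within$est_count[2] / total else 0
  diags <- c(second_lineage_fraction = second_lin_frac,
             second_allele_fraction = second_allele_frac)
  if (second_allele_frac >= zygosity_threshold - eps) {
    new_genotype_call(locus, within$ref_id[1:2], homozygous = FALSE,
                      lineage_het = FALSE, confirmed = FALSE,
                      diagnostics = diags)
  } else {
    new_genotype_call(locus, within$ref_id[1], homozygous = TRUE,
                      lineage_het = FALSE, confirmed = TRUE,
                      diagnostics = diags)
  }
}

#' Confirm or reject a provisional heterozygote
#'
#' Guards against false heterozygotes caused by extensive similarity between
#' the two called alleles: every fragment whose compatibility set (in the
#' candidate-index alignment) contains the lead allele is removed, the
#' remaining fragments are re-mapped against an index holding only the two
#' called alleles, and the second allele is kept only if its re-estimated
#' count reaches `min_fraction` (default 1%, inclusive) of the original
#' locus read count; otherwise the genotype collapses to a homozygote for
#' the lead allele.
#'
#' @param call A provisional heterozygous `genotype_call` (homozygous calls
#'   are returned unchanged).
#' @param aln The `pseudoalignment` of the fragments against the candidate
#'   index (the alignment `call` was derived from).
#' @param reads1,reads2 The fragment mate sequences (same order as `aln`).
#' @param sequences Named character vector giving the sequence of at least
#'   the two called alleles.
#' @param locus_total Original estimated read count of the locus.
#' @param min_fraction Minimum retained fraction for the second allele.
#' @param k,tol,max_iter Mapping and EM parameters.
#' @return The final `genotype_call` with `confirmed = TRUE` and the observed
#'   fraction recorded in `diagnostics["confirm_fraction"]`.
#' @export
confirm_heterozygote <- function(call, aln, reads1, reads2 = NULL, sequences,
                                 locus_total, min_fraction = 0.01, k = 31L,
                                 tol = 0.01, max_iter = 1000L) {
  stopifnot(inherits(call, "genotype_call"))
  if (isTRUE(call$homozygous) || length(call$alleles) < 2) return(call)
  lead <- call$alleles[1]
  second <- call$alleles[2]
  if (!all(c(lead, second) %in% names(sequences))) {
    stop("sequences must cover both called alleles", call. = FALSE)
  }

  lead_idx <- match(lead, aln$ref_ids)
  class_has_lead <- vapply(aln$class_ref_idx, function(i) lead_idx %in% i,
                           logical(1))
  drop <- aln$frag_class > 0 & class_has_lead[pmax(aln$frag_class, 1L)]
  keep <- !drop

  collapse <- function(frac) {
    new_genotype_call(call$locus, lead, homozygous = TRUE,
                      lineage_het = call$lineage_heterozygous, confirmed = TRUE,
                      diagnostics = c(call$diagnostics,
                                      confirm_fraction = frac))
  }
  if (!any(keep) || locus_total <= 0) return(collapse(0))

  pair <- reference_set(c(lead, second), sequences[c(lead, second)],
                        is_hla = TRUE, locus = call$locus)
  idx2 <- build_kmer_index(pair, k = k)
  aln2 <- pseudoalign(idx2, reads1[keep],
                      if (is.null(reads2)) NULL else reads2[keep])
  eff <- effective_length(idx2$ref_lengths, 1)  # raw lengths; counts only
  ab2 <- em_quantify(aln2$classes, eff, tol = tol, max_iter = max_iter)
  second_count <- ab2$est_count[ab2$ref_id == second]
  frac <- second_count / locus_total
  if (frac >= min_fraction - 1e-12) {
    out <- call
    out$confirmed <- TRUE
    out$diagnostics <- c(call$diagnostics, confirm_fraction = unname(frac))
    out
  } else {
    collapse(unname(frac))
  }
}

#' Two-stage in-silico HLA genotyping of one sample
#'
#' Orchestrates the full typing pipeline: (1) quantify all fragments against
#' the HLA-diversity-supplemented index; (2) per locus, select up to `n_top`
#' candidate alleles through the intra-lineage filter; (3) build a
#' per-individual candidate index (the candidates of every locus jointly,
#' plus all non-HLA transcripts to absorb off-target reads) and re-quantify;
#' (4) call zygosity per locus and (5) confirm provisional heterozygotes by
#' lead-read removal. Loci with no mapped reads are reported as no-calls.
#'
#' @param reads1,reads2 Fragment mate sequences.
#' @param supplemented The supplemented [reference_set()]
#'   (from [build_supplemented_reference()]).
#' @param index Optional prebuilt [build_kmer_index()] over `supplemented`.
#' @param loci Loci to type; default all HLA loci in `supplemented`.
#' @param n_top,intra_lineage_threshold Candidate selection parameters.
#' @param lineage_threshold,zygosity_threshold Zygosity thresholds.
#' @param min_confirm_fraction Heterozygote confirmation threshold.
#' @param k K-mer size.
#' @param mean_fragment Mean fragment length for effective lengths.
#' @param tol,max_iter EM parameters.
#' @return Named list of `genotype_call` objects (class `genotype_calls`),
#'   one per locus.
#' @export
genotype_sample <- function(reads1, reads2 = NULL, supplemented, index = NULL,
                            loci = NULL, n_top = 5L,
                            intra_lineage_threshold = 0.25,
                            lineage_threshold = 0.15,
                            zygosity_threshold = 0.15,
                            min_confirm_fraction = 0.01,
                            k = 31L, mean_fragment = 250, tol = 0.01,
                            max_iter = 1000L) {
  if (length(reads1) == 0) stop("empty fragment stream", call. = FALSE)
  supplemented <- validate_reference_set(supplemented)
  if (is.null(index)) index <- build_kmer_index(supplemented, k = k)
  if (is.null(loci)) loci <- unique(supplemented$locus[supplemented$is_hla])
  locus_map <- reference_locus_map(supplemented)

  aln1 <- pseudoalign(index, reads1, reads2)
  eff <- effective_length(index$ref_lengths, mean_fragment)
  ab1 <- em_quantify(aln1$classes, eff, tol = tol, max_iter = max_iter)

  no_call <- function(locus) {
    new_genotype_call(locus, character(0), homozygous = NA,
                      lineage_het = NA, confirmed = FALSE)
  }

  cands <- lapply(loci, function(l) {
    rows <- ab1[!is.na(locus_map[ab1$ref_id]) & locus_map[ab1$ref_id] == l, ]
    top_candidates(rows, n = n_top,
                   intra_lineage_threshold = intra_lineage_threshold)
  })
  names(cands) <- loci
  all_cands <- unlist(cands, use.names = FALSE)

  calls <- stats::setNames(vector("list", length(loci)), loci)
  if (length(all_cands) == 0) {
    calls[] <- lapply(loci, no_call)
    return(structure(calls, class = "genotype_calls"))
  }

  cand_refs <- supplemented[!supplemented$is_hla |
                              supplemented$id %in% all_cands, ]
  idx2 <- build_kmer_index(cand_refs, k = k)
  aln2 <- pseudoalign(idx2, reads1, reads2)
  eff2 <- effective_length(idx2$ref_lengths, mean_fragment)
  ab2 <- em_quantify(aln2$classes, eff2, tol = tol, max_iter = max_iter)
  seqs <- stats::setNames(supplemented$sequence, supplemented$id)

  for (l in loci) {
    if (length(cands[[l]]) == 0) { calls[[l]] <- no_call(l); next }
    requant <- ab2[ab2$ref_id %in% cands[[l]], ]
    locus_total <- sum(requant$est_count)
    if (locus_total <= 0) { calls[[l]] <- no_call(l); next }
    call <- call_genotype(requant, lineage_threshold = lineage_threshold,
                          zygosity_threshold = zygosity_threshold)
    if (!call$homozygous) {
      call <- confirm_heterozygote(call, aln2, reads1, reads2, seqs,
                                   locus_total = locus_total,
                                   min_fraction = min_confirm_fraction,
                                   k = k, tol = tol, max_iter = max_iter)
    }
    calls[[l]] <- call
  }
  structure(calls, class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  for (call in x) print(call)
  invisible(x)
}

#' Tabulate genotype calls
#'
#' @param calls A `genotype_calls` list from [genotype_sample()].
#' @param sample Sample identifier to attach.
#' @return Tibble with `sample`, `locus`, `allele1`, `allele2` (`NA` for
#'   homozygotes and no-calls), `homozygous`, `lineage_heterozygous`,
#'   `confirmed`.
#' @export
genotype_table <- function(calls, sample = "sample1") {
  rows <- lapply(calls, function(g) {
    tibble::tibble(
      sample = sample, locus = g$locus,
      allele1 = if (length(g$alleles) >= 1) g$alleles[1] else NA_character_,
      allele2 = if (length(g$alleles) >= 2) g$alleles[2] else NA_character_,
      homozygous = g$homozygous,
      lineage_heterozygous = g$lineage_heterozygous,
      confirmed = g$confirmed
    )
  })
  dplyr::bind_rows(rows)
}

#' Typing concordance against truth genotypes
#'
#' Each called allele is compared to the truth alleles truncated to
#' `resolution_fields` name fields, using the better of the two bipartite
#' matchings of the two alleles at each (sample, locus). A homozygous call
#' contributes its single allele against both truth copies. Concordance is
#' the number of matched alleles divided by the total number of truth
#' alleles; loci present in the truth but missing from the calls count as
#' fully discordant.
#'
#' @param calls Genotype table ([genotype_table()] output, possibly row-bound
#'   over samples) or a single `genotype_calls` list.
#' @param truth Tibble with `sample` (optional for single-sample input),
#'   `locus`, `allele1`, `allele2`.
#' @param resolution_fields Name-field resolution of the comparison.
#' @return Overall concordance in \[0, 1\], with a per-locus breakdown in
#'   attribute `by_locus`.
#' @export
typing_concordance <- function(calls, truth, resolution_fields = 2L) {
  if (inherits(calls, "genotype_calls")) calls <- genotype_table(calls)
  if (!"sample" %in% names(truth)) truth$sample <- calls$sample[1]
  trunc2 <- function(x) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x)
    out[ok] <- truncate_allele(x[ok], resolution_fields)
    out
  }
  matched <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    t1 <- trunc2(truth$allele1[i])
    t2 <- trunc2(truth$allele2[i])
    row <- calls[calls$sample == truth$sample[i] &
                   calls$locus == truth$locus[i], ]
    if (nrow(row) == 0 || is.na(row$allele1[1])) {
      message("no call for ", truth$sample[i], " / ", truth$locus[i],
              "; counted as discordant")
      next
    }
    c1 <- trunc2(row$allele1[1])
    c2 <- if (is.na(row$allele2[1])) c1 else trunc2(row$allele2[1])
    matched[i] <- max((t1 == c1) + (t2 == c2), (t1 == c2) + (t2 == c1))
  }
  by_locus <- tapply(matched, truth$locus, sum) /
    (2 * tapply(rep(1, nrow(truth)), truth$locus, sum))
  out <- sum(matched) / (2 * nrow(truth))
  attr(out, "by_locus") <- by_locus
  out
}

#' Write genotype calls to TSV
#'
#' @param calls `genotype_calls` or a genotype table.
#' @param path Output path.
#' @param sample Sample id used when `calls` is a `genotype_calls` list.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(calls, path, sample = "sample1") {
  if (inherits(calls, "genotype_calls")) calls <- genotype_table(calls, sample)
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
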