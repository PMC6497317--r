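#' Impute flanks for a partially sequenced allele
#'
#' Many database alleles are sequenced only over the antigen-recognition-site
#' exons. Excluding them would discard reads near the exon boundaries, so a
#' partial allele is completed by locating its available region within the
#' closest fully sequenced allele of the same locus (best edit-distance
#' placement of the partial against each candidate, ends-free on the
#' candidate) and splicing the partial's own sequence into that candidate's
#' flanks. Closeness is the minimum edit distance over the partial's
#' available region, normalized by its length; ties between equally close
#' candidates are broken by the lexicographically smallest allele name so
#' builds are deterministic.
#'
#' @param partial One-row allele table (as from [read_imgt_fasta()]) holding
#'   the partial allele.
#' @param candidates Allele table of complete candidates at the same locus.
#' @param max_distance Maximum tolerated normalized distance of the partial's
#'   region to its best candidate; beyond this the region is considered not
#'   locatable and completion fails.
#' @return A one-row allele table: the chosen candidate's sequence with the
#'   partial's region substituted in verbatim, `is_complete = TRUE`,
#'   `source = "imputed_flanks"`.
#' @export
complete_partial_sequence <- function(partial, candidates, max_distance = 0.5) {
  stopifnot(is.data.frame(partial), nrow(partial) == 1)
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no complete candidate alleles available to complete '",
         partial$allele, "'", call. = FALSE)
  }
  if (!all(candidates$is_complete)) {
    stop("all candidates must be complete sequences", call. = FALSE)
  }
  if (!all(candidates$locus == partial$locus)) {
    stop("candidates must be at the same locus as the partial allele",
         call. = FALSE)
  }
  # order first so equal-distance ties resolve to the smallest allele name
  candidates <- candidates[order(candidates$allele), ]
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  pat <- Biostrings::DNAString(partial$sequence)
  best <- NULL
  for (i in seq_len(nrow(candidates))) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = pat,
      subject = Biostrings::DNAString(candidates$sequence[i]),
      type = "global-local",
      substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = 1
    )
    dist <- -Biostrings::score(aln)  # edit distance of the best placement
    if (is.null(best) || dist < best$dist) {
      rng <- Biostrings::subject(aln)
      best <- list(dist = dist, i = i,
                   start = Biostrings::start(rng), end = Biostrings::end(rng))
    }
  }
  norm_dist <- best$dist / nchar(partial$sequence)
  if (norm_dist > max_distance) {
    stop("partial region of '", partial$allele,
         "' not locatable in any candidate (normalized distance ",
         signif(norm_dist, 3), " > ", max_distance, ")", call. = FALSE)
  }
  cand <- candidates[best$i, ]
  hybrid <- paste0(substr(cand$sequence, 1L, best$start - 1L),
                   partial$sequence,
                   substr(cand$sequence, best$end + 1L, nchar(cand$sequence)))
  out <- partial
  out$sequence <- hybrid
  out$length <- nchar(hybrid)
  out$stated_length <- NA_integer_
  out$is_complete <- TRUE
  out$source <- "imputed_flanks"
  out$closest_complete <- cand$allele
  out$completion_distance <- norm_dist
  out
}

#' Complete every partial allele in a table
#'
#' Applies [complete_partial_sequence()] to each incomplete record, using the
#' complete alleles of the same locus as candidates. Loci with no complete
#' allele raise an error.
#'
#' @param alleles Allele table as returned by [read_imgt_fasta()].
#' @inheritParams complete_partial_sequence
#' @return The allele table with all records complete; imputed records carry
#'   `source = "imputed_flanks"`.
#' @export
complete_all <- function(alleles, max_distance = 0.5) {
  if (all(alleles$is_complete)) return(alleles)
  done <- lapply(seq_len(nrow(alleles)), function(i) {
    if (alleles$is_complete[i]) return(alleles[i, ])
    cands <- alleles[alleles$is_complete & alleles$locus == alleles$locus[i], ]
    complete_partial_sequence(alleles[i, ], cands, max_distance = max_distance)
  })
  dplyr::bind_rows(done)
}
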