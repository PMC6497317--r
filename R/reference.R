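#' Construct a reference set
#'
#' A reference set is the unit the index builders and quantifiers operate on:
#' an ordered table of named nucleotide sequences, each flagged as an HLA
#' allele record (with its locus) or an ordinary transcript.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of nucleotide sequences (A/C/G/T/N).
#' @param is_hla Logical vector; `TRUE` for HLA allele records.
#' @param locus Character vector; the locus of each HLA record, `NA` for
#'   non-HLA records.
#' @return A tibble of class `reference_set` with columns `id`, `sequence`,
#'   `is_hla`, `locus`.
#' @examples
#' reference_set(c("TX1", "A*01:01"), c("ACGTACGTACGT", "ACGTTTTTACGT"),
#'               is_hla = c(FALSE, TRUE), locus = c(NA, "A"))
#' @export
reference_set <- function(id, sequence, is_hla = FALSE, locus = NA_character_) {
  out <- tibble::tibble(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    is_hla = rep_len(is_hla, length(id)),
    locus = rep_len(as.character(locus), length(id))
  )
  validate_reference_set(out)
}

validate_reference_set <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("id", "sequence", "is_hla", "locus") %in% names(x)))
  if (anyDuplicated(x$id)) {
    stop("duplicate reference ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "), call. = FALSE)
  }
  if (any(x$is_hla & is.na(x$locus))) {
    stop("every HLA record must carry a locus", call. = FALSE)
  }
  if (any(!x$is_hla & !is.na(x$locus))) {
    stop("non-HLA records must have locus NA", call. = FALSE)
  }
  class(x) <- unique(c("reference_set", class(x)))
  x
}

#' Supplement a transcriptome with the HLA allele diversity
#'
#' Removes the annotated HLA transcripts from a reference transcriptome and
#' inserts one record per known HLA allele in their place, producing the
#' index used for in-silico typing. Record identifiers for the inserted
#' alleles are the full allele names.
#'
#' @param transcriptome A [reference_set()] of transcript sequences.
#' @param hla_transcript_ids Ids of the transcriptome records annotated as
#'   HLA transcripts; must all be present in `transcriptome`.
#' @param alleles An allele table as returned by [read_imgt_fasta()] (columns
#'   `allele`, `locus`, `sequence`), or any data frame with those columns.
#' @return A `reference_set` with
#'   `nrow(transcriptome) - length(hla_transcript_ids) + nrow(alleles)` records;
#'   non-HLA sequences are carried over byte-identically.
#' @export
build_supplemented_reference <- function(transcriptome, hla_transcript_ids,
                                         alleles) {
  transcriptome <- validate_reference_set(transcriptome)
  missing <- setdiff(hla_transcript_ids, transcriptome$id)
  if (length(missing) > 0) {
    stop("hla_transcript_ids absent from transcriptome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(alleles$allele)) {
    stop("duplicated allele names: ",
         paste(unique(alleles$allele[duplicated(alleles$allele)]),
               collapse = ", "), call. = FALSE)
  }
  kept <- transcriptome[!transcriptome$id %in% hla_transcript_ids, ]
  if (nrow(alleles) > 0) {
    added <- tibble::tibble(
      id = alleles$allele,
      sequence = toupper(alleles$sequence),
      is_hla = TRUE,
      locus = alleles$locus
    )
    kept <- dplyr::bind_rows(kept[, c("id", "sequence", "is_hla", "locus")],
                             added)
  }
  validate_reference_set(kept)
}

#' Read and write reference sets
#'
#' A reference set is serialized as a FASTA file (sequences wrapped at 60
#' columns) plus a TSV sidecar recording `id`, `is_hla`, and `locus`.
#'
#' @param refs A [reference_set()].
#' @param fasta,tsv File paths for the FASTA and the sidecar TSV.
#' @return `write_reference_set()` returns `refs` invisibly;
#'   `read_reference_set()` returns a `reference_set`.
#' @export
write_reference_set <- function(refs, fasta, tsv = paste0(fasta, ".tsv")) {
  refs <- validate_reference_set(refs)
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- refs$id
  Biostrings::writeXStringSet(seqs, fasta, width = 60L)
  utils::write.table(refs[, c("id", "is_hla", "locus")], tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(refs)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(fasta, tsv = paste0(fasta, ".tsv")) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  meta$locus <- as.character(meta$locus)
  meta$locus[meta$locus %in% c("NA", "")] <- NA_character_
  ord <- match(names(seqs), meta$id)
  if (anyNA(ord)) stop("FASTA and sidecar TSV disagree on record ids",
                       call. = FALSE)
  reference_set(names(seqs), unname(as.character(seqs)),
                is_hla = meta$is_hla[ord], locus = meta$locus[ord])
}

#' Map reference ids to loci
#'
#' @param refs A [reference_set()].
#' @return Named character vector: id -> locus (`NA` for non-HLA records).
#' @export
reference_locus_map <- function(refs) {
  stats::setNames(refs$locus, refs$id)
}
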