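#' Read an allele FASTA in the IMGT/HLA header dialect
#'
#' The IMGT/HLA database distributes allele nucleotide sequences with headers
#' of the form `>HLA:HLA00001 A*01:01:01:01 3503 bp` (accession, allele name,
#' stated length). Many alleles are only partially sequenced (typically the
#' antigen-recognition-site exons), so each record is flagged as complete or
#' partial; absent an explicit annotation, a record is considered complete
#' when its length reaches `complete_frac` of the longest sequence at its
#' locus.
#'
#' @param path Path to the FASTA file.
#' @param dialect `"imgt"` for the accession/name/length header dialect;
#'   `"plain"` to accept bare `>NAME` headers (the full header token is then
#'   taken as the allele name and no accession or stated length is parsed).
#' @param complete_frac Fraction of the locus-wise maximum length at or above
#'   which a record counts as a complete coding sequence.
#' @return A tibble with one row per record: `allele`, `accession`, `locus`,
#'   `lineage`, `sequence` (uppercased), `length`, `stated_length`,
#'   `is_complete`, and `source` (`"observed"` on read).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">HLA:HLA00001 A*01:01 12 bp", "ACGTACGTACGT"), fa)
#' read_imgt_fasta(fa)
#' @export
read_imgt_fasta <- function(path, dialect = c("imgt", "plain"),
                            complete_frac = 0.9) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    return(tibble::tibble(
      allele = character(), accession = character(), locus = character(),
      lineage = character(), sequence = character(), length = integer(),
      stated_length = integer(), is_complete = logical(), source = character()
    ))
  }
  headers <- names(seqs)
  if (dialect == "imgt") {
    m <- regmatches(headers,
                    regexec("^(\\S+)\\s+(\\S+)\\s+(\\d+)\\s+bp\\s*$", headers))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) {
      stop("header does not match the IMGT dialect at line ",
           header_line_number(path, headers[which(bad)[1]]), ": '>",
           headers[which(bad)[1]], "'", call. = FALSE)
    }
    accession <- vapply(m, `[`, character(1), 2L)
    allele <- vapply(m, `[`, character(1), 3L)
    stated <- as.integer(vapply(m, `[`, character(1), 4L))
    mismatch <- stated != Biostrings::width(seqs)
    if (any(mismatch)) {
      i <- which(mismatch)[1]
      stop("stated length (", stated[i], " bp) does not match sequence length (",
           Biostrings::width(seqs)[i], ") for record '", allele[i], "'",
           call. = FALSE)
    }
  } else {
    allele <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
    accession <- NA_character_
    stated <- NA_integer_
  }
  parsed <- parse_allele_name(allele)
  out <- tibble::tibble(
    allele = allele,
    accession = accession,
    locus = parsed$locus,
    lineage = parsed$lineage,
    sequence = toupper(unname(as.character(seqs))),
    length = Biostrings::width(seqs),
    stated_length = stated,
    source = "observed"
  )
  locus_max <- stats::ave(out$length, out$locus, FUN = max)
  out$is_complete <- out$length >= complete_frac * locus_max
  out[, c("allele", "accession", "locus", "lineage", "sequence", "length",
          "stated_length", "is_complete", "source")]
}

header_line_number <- function(path, header) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(lines == paste0(">", header))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Write an allele table as IMGT-dialect FASTA
#'
#' @param alleles Allele table as returned by [read_imgt_fasta()].
#' @param path Output FASTA path; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_imgt_fasta <- function(alleles, path) {
  seqs <- Biostrings::DNAStringSet(alleles$sequence)
  acc <- alleles$accession
  acc[is.na(acc)] <- paste0("SYN:", sprintf("%05d", seq_len(nrow(alleles))[is.na(acc)]))
  names(seqs) <- paste(acc, alleles$allele, Biostrings::width(seqs), "bp")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
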