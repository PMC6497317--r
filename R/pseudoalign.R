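#' Build a canonical k-mer index over a reference set
#'
#' Every position of every reference contributes its canonical k-mer (the
#' lexicographic minimum of the k-mer and its reverse complement), so mapping
#' is strand-symmetric by construction. k-mers containing non-ACGT bases are
#' not indexed. Records shorter than `k` are skipped with a warning.
#'
#' @param refs A [reference_set()], or any data frame with `id` and
#'   `sequence` columns.
#' @param k Odd k-mer size between 11 and 31. The default 31 is the common
#'   choice for transcriptome pseudoalignment.
#' @return An object of class `kmer_index` (external pointer plus `k`,
#'   `ref_ids`, `ref_lengths`). Indexes hold compiled state and are rebuilt,
#'   not serialized.
#' @export
build_kmer_index <- function(refs, k = 31L) {
  k <- as.integer(k)
  if (k < 11L || k > 31L || k %% 2L == 0L) {
    stop("k must be an odd integer between 11 and 31", call. = FALSE)
  }
  stopifnot(is.data.frame(refs), all(c("id", "sequence") %in% names(refs)))
  short <- nchar(refs$sequence) < k
  if (any(short)) {
    warning("skipping ", sum(short), " reference(s) shorter than k = ", k,
            ": ", paste(utils::head(refs$id[short], 5), collapse = ", "),
            call. = FALSE)
  }
  ptr <- kmer_index_build_cpp(refs$id, toupper(refs$sequence), k)
  structure(
    list(ptr = ptr, k = k, ref_ids = refs$id,
         ref_lengths = stats::setNames(nchar(refs$sequence), refs$id)),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- kmer_index_info_cpp(x$ptr)
  cat("k-mer index: k =", x$k, "|", length(x$ref_ids), "references |",
      format(info$n_kmers, big.mark = ","), "distinct k-mers\n")
  invisible(x)
}

#' Map a single fragment to its compatible references
#'
#' Per mate, compatibility is the intersection of the index entry sets over
#' the mate's k-mers, skipping k-mers absent from the index (which tolerates
#' sequencing errors). The fragment's compatibility is the intersection of
#' the two mates' sets when both have at least one indexed k-mer, otherwise
#' the single informative mate's set. An empty result means unmapped.
#'
#' @param read1 First mate sequence.
#' @param read2 Optional second mate sequence.
#' @param index A [build_kmer_index()] object.
#' @return Character vector of compatible reference ids (possibly empty).
#' @export
map_fragment <- function(read1, read2 = NULL, index) {
  res <- map_fragments_cpp(index$ptr, read1,
                           if (is.null(read2)) NULL else read2)
  if (length(res$class_refs) == 0) return(character(0))
  index$ref_ids[res$class_refs[[1]]]
}

#' Pseudoalign fragments and collect equivalence classes
#'
#' Maps every fragment and aggregates fragments with identical compatibility
#' sets into equivalence classes, the unit of input for EM quantification.
#' Class counts, the unmapped count and the too-short count always sum to
#' the number of fragments streamed.
#'
#' @param index A [build_kmer_index()] object.
#' @param reads1 Character vector of first-mate sequences.
#' @param reads2 Optional character vector of second-mate sequences.
#' @return A list of class `pseudoalignment`: `classes` (tibble with list
#'   column `refs` and `count`), `frag_class` (per-fragment class id, 0 =
#'   unmapped, -1 = too short), `class_ref_idx` (internal integer form),
#'   `n_unmapped`, `n_too_short`, `n_fragments`, `ref_ids`.
#' @export
pseudoalign <- function(index, reads1, reads2 = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  res <- map_fragments_cpp(index$ptr, reads1, reads2)
  classes <- tibble::tibble(
    refs = lapply(res$class_refs, function(i) index$ref_ids[i]),
    count = res$class_count
  )
  structure(
    list(classes = classes,
         class_ref_idx = res$class_refs,
         frag_class = res$frag_class,
         n_unmapped = res$n_unmapped,
         n_too_short = res$n_too_short,
         n_fragments = length(reads1),
         ref_ids = index$ref_ids),
    class = "pseudoalignment"
  )
}

#' @export
print.pseudoalignment <- function(x, ...) {
  cat("pseudoalignment:", x$n_fragments, "fragments,",
      nrow(x$classes), "equivalence classes,",
      x$n_unmapped, "unmapped,", x$n_too_short, "too short\n")
  invisible(x)
}

#' Collect equivalence classes from paired reads
#'
#' Convenience wrapper around [pseudoalign()] returning just the class table
#' and the unmapped/too-short tallies.
#'
#' @inheritParams pseudoalign
#' @return List with `classes`, `n_unmapped`, `n_too_short`.
#' @export
collect_equivalence_classes <- function(reads1, reads2 = NULL, index) {
  aln <- pseudoalign(index, reads1, reads2)
  list(classes = aln$classes, n_unmapped = aln$n_unmapped,
       n_too_short = aln$n_too_short)
}

#' Counts from uniquely mapped fragments only
#'
#' The comparator mode that emulates conventional unique-read counting: all
#' mass in multi-reference classes is discarded and only singleton classes
#' contribute.
#'
#' @param classes Equivalence-class tibble (`refs` list column, `count`).
#' @param ref_ids Optional universe of reference ids; ids with no unique
#'   reads are reported as 0.
#' @return Named numeric vector of per-reference unique-read counts.
#' @export
unique_counts <- function(classes, ref_ids = NULL) {
  singleton <- lengths(classes$refs) == 1L
  ids <- vapply(classes$refs[singleton], `[`, character(1), 1L)
  counts <- tapply(classes$count[singleton], ids, sum)
  if (is.null(ref_ids)) {
    ref_ids <- sort(unique(unlist(classes$refs)))
  }
  out <- stats::setNames(numeric(length(ref_ids)), ref_ids)
  out[names(counts)] <- as.numeric(counts)
  out
}

#' Serialize equivalence classes to TSV
#'
#' @param classes Equivalence-class tibble.
#' @param path Output TSV path (columns `refs`, comma-joined, and `count`).
#' @return `path` invisibly; `read_equivalence_classes()` returns the tibble.
#' @export
write_equivalence_classes <- function(classes, path) {
  utils::write.table(
    data.frame(refs = vapply(classes$refs, paste, character(1), collapse = ","),
               count = classes$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_equivalence_classes
#' @export
read_equivalence_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::tibble(refs = strsplit(df$refs, ",", fixed = TRUE),
                 count = as.numeric(df$count))
}

#' Read and write paired FASTQ
#'
#' Thin wrappers over Biostrings FASTQ IO; `read_paired_fastq()` returns the
#' mate sequences as character vectors, which is the representation the
#' mapper consumes. Base qualities are not used by the pipeline.
#'
#' @param r1,r2 FASTQ paths (optionally gzipped on read).
#' @param reads1,reads2 Character vectors of mate sequences.
#' @param ids Read names; generated when `NULL`.
#' @param quality Constant quality character used on write.
#' @return `read_paired_fastq()`: list with `reads1`, `reads2`, `ids`.
#' @export
read_paired_fastq <- function(r1, r2 = NULL) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  out <- list(reads1 = unname(as.character(s1)), ids = names(s1))
  if (!is.null(r2)) {
    s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
    if (length(s2) != length(s1)) {
      stop("mate files have different numbers of reads", call. = FALSE)
    }
    out$reads2 <- unname(as.character(s2))
  }
  out[c("reads1", "reads2", "ids")]
}

#' @rdname read_paired_fastq
#' @export
write_paired_fastq <- function(reads1, reads2, r1, r2, ids = NULL,
                               quality = "I") {
  if (is.null(ids)) ids <- sprintf("frag%06d", seq_along(reads1))
  write_one <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep(quality, nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                                compress = endsWith(path, ".gz"))
  }
  write_one(reads1, r1)
  if (!is.null(reads2)) write_one(reads2, r2)
  invisible(c(r1, r2))
}
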