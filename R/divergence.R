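#' Sequence divergence as the proportion of mismatches
#'
#' Divergence between two nucleotide sequences is the Levenshtein edit
#' distance divided by the length of the longer sequence, giving a symmetric
#' proportion in \[0, 1\] that is 0 exactly for identical sequences. This is
#' the "proportion of mismatches" used to relate an individual's HLA alleles
#' to the allele present in the reference assembly. `N` bases are treated as
#' mismatching everything, including another `N` (ambiguity never counts as
#' agreement).
#'
#' @param a,b Non-empty nucleotide strings.
#' @return A single proportion in \[0, 1\].
#' @examples
#' divergence("ACGT", "ACGA")  # 0.25
#' divergence("AC", "A")       # 0.5
#' @export
divergence <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) {
    stop("divergence is undefined for empty sequences", call. = FALSE)
  }
  # distinct placeholders force N to mismatch every base, N included
  a2 <- chartr("Nn", "!!", a)
  b2 <- chartr("Nn", "??", b)
  d <- utils::adist(a2, b2)[1, 1]
  d / max(nchar(a), nchar(b))
}

#' Divergence of each allele to a designated reference allele
#'
#' @param alleles Character vector of sequences.
#' @param reference A single reference sequence.
#' @return Numeric vector of divergences.
#' @export
divergence_to_reference <- function(alleles, reference) {
  vapply(alleles, divergence, numeric(1), b = reference, USE.NAMES = FALSE)
}
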