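#' Parse HLA allele names
#'
#' HLA allele names follow the colon-delimited nomenclature
#' `LOCUS*F1:F2[:F3[:F4]]` (e.g. `"DRB1*13:01:02"`). The token before `*` is
#' the locus; the first numeric field defines the allele *lineage*
#' (`"DRB1*13"`), the group of evolutionarily related alleles the field's
#' literature aggregates over when per-allele sample sizes are too sparse.
#'
#' @param raw Character vector of allele names.
#' @return A tibble with one row per name and columns `raw`, `locus`,
#'   `lineage`, `n_fields`, and `fields` (a list column of the field tokens).
#' @examples
#' parse_allele_name("A*01:01:01:01")
#' parse_allele_name(c("C*04:01", "DRB1*13:01"))
#' @export
parse_allele_name <- function(raw) {
  stopifnot(is.character(raw))
  star <- regexpr("*", raw, fixed = TRUE)
  bad <- vapply(gregexpr("*", raw, fixed = TRUE), function(m) {
    sum(m > 0) != 1L
  }, logical(1))
  if (any(bad | star <= 1L)) {
    offender <- raw[which(bad | star <= 1L)[1]]
    stop("malformed allele name (need exactly one '*' with a locus before it): '",
         offender, "'", call. = FALSE)
  }
  locus <- substr(raw, 1L, star - 1L)
  rest <- substr(raw, star + 1L, nchar(raw))
  fields <- strsplit(rest, ":", fixed = TRUE)
  empty <- vapply(fields, function(f) length(f) == 0L || any(!nzchar(f)),
                  logical(1)) | !nzchar(rest) | endsWith(raw, ":")
  if (any(empty)) {
    stop("malformed allele name (empty field): '", raw[which(empty)[1]], "'",
         call. = FALSE)
  }
  tibble::tibble(
    raw = raw,
    locus = locus,
    lineage = paste0(locus, "*", vapply(fields, `[`, character(1), 1L)),
    n_fields = lengths(fields),
    fields = fields
  )
}

#' Locus, lineage, and field truncation helpers
#'
#' Vectorised accessors over allele names. `truncate_allele()` reduces names
#' to at most `fields` name fields, the operation used to compare genotype
#' calls at e.g. two-field resolution.
#'
#' @param raw Character vector of allele names.
#' @param fields Number of name fields to keep.
#' @return Character vector of the same length as `raw`.
#' @examples
#' allele_lineage("C*04:01")
#' truncate_allele("A*01:01:01:01", 2)
#' @export
allele_lineage <- function(raw) parse_allele_name(raw)$lineage

#' @rdname allele_lineage
#' @export
allele_locus <- function(raw) parse_allele_name(raw)$locus

#' @rdname allele_lineage
#' @export
truncate_allele <- function(raw, fields = 2L) {
  parsed <- parse_allele_name(raw)
  vapply(seq_along(raw), function(i) {
    f <- parsed$fields[[i]]
    paste0(parsed$locus[i], "*",
           paste(f[seq_len(min(fields, length(f)))], collapse = ":"))
  }, character(1))
}
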