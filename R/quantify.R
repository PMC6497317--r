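#' Effective length of a reference for fragment sampling
#'
#' The number of distinct start positions a fragment of the mean length can
#' occupy: `max(length - mu + 1, 1)`, with the mean fragment length
#' pre-clamped to at least 1 (so `mean_fragment = 0` gives the full length).
#'
#' @param length Integer reference length(s).
#' @param mean_fragment Mean fragment length of the library.
#' @return Positive numeric vector of effective lengths.
#' @examples
#' effective_length(1000, 250)  # 751
#' effective_length(100, 250)   # clamped to 1
#' @export
effective_length <- function(length, mean_fragment) {
  stopifnot(all(length >= 1))
  mu <- max(mean_fragment, 1)
  pmax(length - mu + 1, 1)
}

#' EM abundance estimation over equivalence classes
#'
#' Maximum-likelihood assignment of multi-mapping fragments: a fragment is
#' modelled as drawn from reference t with probability proportional to
#' `theta_t`, uniformly over `eff_length_t` start positions, so the class
#' likelihood is `sum_c n_c log(sum_{t in c} theta_t / l_t)` (up to the
#' normalising total). The EM update is
#' `theta_t <- sum_c n_c (theta_t/l_t) / sum_{u in c} (theta_u/l_u)`,
#' iterated until the largest change in read-count space falls below `tol`.
#' The likelihood is non-decreasing at every iteration (asserted when
#' `debug = TRUE`). References present in no class get zero counts rather
#' than being dropped.
#'
#' @param classes Equivalence-class tibble (`refs` list column, `count`), as
#'   produced by [pseudoalign()].
#' @param eff_lengths Named positive numeric vector of effective lengths; its
#'   names define the reference universe and must cover every class member.
#' @param tol Convergence tolerance in read counts.
#' @param max_iter Iteration cap.
#' @param debug Assert likelihood monotonicity each iteration and record the
#'   likelihood trace.
#' @return Tibble (lexicographic `ref_id` order) with `ref_id`, `est_count`,
#'   `eff_length`, `tpm`. Attributes: `iterations`, `converged`, and (debug)
#'   `loglik_trace`. `sum(est_count)` equals the mapped fragment total;
#'   `sum(tpm)` is 1e6 whenever any read maps.
#' @export
em_quantify <- function(classes, eff_lengths, tol = 0.01, max_iter = 1000L,
                        debug = FALSE) {
  stopifnot(tol > 0, !is.null(names(eff_lengths)))
  if (any(eff_lengths <= 0)) {
    stop("effective lengths must be positive", call. = FALSE)
  }
  refs <- sort(names(eff_lengths))
  zero_result <- function() {
    out <- tibble::tibble(ref_id = refs, est_count = 0,
                          eff_length = as.numeric(eff_lengths[refs]), tpm = 0)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    out
  }
  if (is.null(classes) || nrow(classes) == 0) return(zero_result())

  members <- unique(unlist(classes$refs))
  unknown <- setdiff(members, refs)
  if (length(unknown) > 0) {
    stop("class members without an effective length: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  active <- sort(members)
  n_active <- length(active)
  counts <- as.numeric(classes$count)
  N <- sum(counts)
  if (N == 0) return(zero_result())
  ell <- as.numeric(eff_lengths[active])

  # sparse class-by-reference membership
  ridx <- lapply(classes$refs, match, table = active)
  M <- Matrix::sparseMatrix(
    i = rep.int(seq_along(ridx), lengths(ridx)),
    j = unlist(ridx),
    x = 1,
    dims = c(nrow(classes), n_active)
  )

  theta <- rep(N / n_active, n_active)
  # class log-likelihood at fixed total counts (the EM's objective)
  loglik <- function(w) sum(counts * log(as.vector(M %*% w)))
  trace <- if (debug) numeric(0) else NULL
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- theta / ell
    denom <- as.vector(M %*% w)
    theta_new <- w * as.vector(Matrix::crossprod(M, counts / denom))
    if (debug) {
      ll <- loglik(w)
      if (ll < ll_prev - 1e-9 * abs(ll_prev)) {
        stop("EM likelihood decreased at iteration ", iter, call. = FALSE)
      }
      trace <- c(trace, ll)
      ll_prev <- ll
    }
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  w <- theta / ell
  est <- stats::setNames(numeric(length(refs)), refs)
  est[active] <- theta
  wfull <- stats::setNames(numeric(length(refs)), refs)
  wfull[active] <- w
  out <- tibble::tibble(
    ref_id = refs,
    est_count = as.numeric(est),
    eff_length = as.numeric(eff_lengths[refs]),
    tpm = 1e6 * as.numeric(wfull) / sum(w)
  )
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  if (debug) attr(out, "loglik_trace") <- trace
  out
}

#' Aggregate estimated counts per HLA locus
#'
#' @param abundances Abundance tibble from [em_quantify()].
#' @param locus_map Named character vector mapping reference id to locus
#'   (`NA` for non-HLA references, which are excluded); must cover every HLA
#'   reference of interest.
#' @return Tibble with `locus` and `est_count` (sum over the locus's
#'   references); empty when no reference maps to a locus.
#' @export
locus_counts <- function(abundances, locus_map) {
  loci <- unname(locus_map[abundances$ref_id])
  keep <- !is.na(loci)
  if (!any(keep)) return(tibble::tibble(locus = character(), est_count = numeric()))
  agg <- tapply(abundances$est_count[keep], loci[keep], sum)
  tibble::tibble(locus = names(agg), est_count = as.numeric(agg))
}

#' Write an abundance table
#'
#' TSV with columns `ref_id`, `locus` (`"."` for non-HLA), `est_count`,
#' `eff_length`, `tpm`, in deterministic lexicographic `ref_id` order.
#'
#' @param abundances Abundance tibble from [em_quantify()].
#' @param path Output path.
#' @param locus_map Optional named id -> locus vector.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundances, path, locus_map = NULL) {
  loc <- if (is.null(locus_map)) NA_character_ else unname(locus_map[abundances$ref_id])
  loc[is.na(loc)] <- "."
  df <- data.frame(ref_id = abundances$ref_id, locus = loc,
                   est_count = abundances$est_count,
                   eff_length = abundances$eff_length,
                   tpm = abundances$tpm)
  df <- df[order(df$ref_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
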