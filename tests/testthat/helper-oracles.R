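# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "")[[1]]),
        collapse = "")
}

# quadratic dynamic-programming Levenshtein distance, N mismatches everything
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      eq <- x[i] == y[j] && x[i] != "N" && y[j] != "N"
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + !eq)
    }
    prev <- cur
  }
  prev[m + 1]
}

# brute-force maximizer of the class likelihood on a simplex grid;
# classes: list of character vectors; counts: numeric; equal effective lengths
grid_ml_counts <- function(classes, counts, refs, step = 0.01) {
  N <- sum(counts)
  k <- length(refs)
  stopifnot(k <= 3)
  grid <- seq(0, 1, by = step)
  best <- NULL
  best_ll <- -Inf
  eval_ll <- function(p) {
    ll <- 0
    for (ci in seq_along(classes)) {
      pc <- sum(p[match(classes[[ci]], refs)])
      if (pc <= 0) return(-Inf)
      ll <- ll + counts[ci] * log(pc)
    }
    ll
  }
  if (k == 1) return(stats::setNames(N, refs))
  if (k == 2) {
    for (a in grid) {
      ll <- eval_ll(c(a, 1 - a))
      if (ll > best_ll) { best_ll <- ll; best <- c(a, 1 - a) }
    }
  } else {
    for (a in grid) for (b in grid[grid <= 1 - a + 1e-12]) {
      ll <- eval_ll(c(a, b, 1 - a - b))
      if (ll > best_ll) { best_ll <- ll; best <- c(a, b, 1 - a - b) }
    }
  }
  stats::setNames(N * best, refs)
}

# exhaustive haplotype-pair search written independently of the package:
# iterates ordered pairs and both per-locus allele pairings explicitly
oracle_haplotype_pair <- function(genotype, panel) {
  loci <- names(genotype)
  best <- Inf
  best_pairs <- list()
  for (h1 in names(panel)) for (h2 in names(panel)) {
    total <- 0
    for (l in loci) {
      g <- genotype[[l]]
      a1 <- panel[[h1]][[l]]; a2 <- panel[[h2]][[l]]
      d1 <- (a1 != g[1]) + (a2 != g[2])
      d2 <- (a1 != g[2]) + (a2 != g[1])
      total <- total + min(d1, d2)
    }
    if (total < best) { best <- total; best_pairs <- list() }
    if (total == best) {
      best_pairs[[length(best_pairs) + 1]] <- sort(c(h1, h2))
    }
  }
  list(mismatches = best, pairs = unique(best_pairs))
}

# tiny allele tibble in the read_imgt_fasta() shape
allele_row <- function(allele, sequence, accession = NA_character_,
                       is_complete = TRUE, source = "observed") {
  parsed <- hlaquant::parse_allele_name(allele)
  tibble::tibble(allele = allele, accession = accession,
                 locus = parsed$locus, lineage = parsed$lineage,
                 sequence = sequence, length = nchar(sequence),
                 stated_length = NA_integer_, is_complete = is_complete,
                 source = source)
}

# equivalence-class tibble from a compact spec like list("A" = 6, "A,B" = 4)
ec <- function(spec) {
  tibble::tibble(refs = strsplit(names(spec), ",", fixed = TRUE),
                 count = as.numeric(unlist(spec)))
}
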