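rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_at <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic HLA-like allele panel
#'
#' Emulates the structure of the HLA allele database at desk scale: per
#' locus, a root sequence (the designated reference allele) and alleles
#' mutated (substitutions only) to a grid of target divergences. Alleles are
#' organized in lineages by divergence cluster: each grid value defines one
#' lineage whose founder carries `round(target * length)` substitutions
#' relative to the root (realized divergence within 10% relative of the
#' target), and sibling alleles within a lineage are the founder plus
#' `sibling_subs` further substitutions. Two designated loci share an
#' identical block of sequence, emulating HLA paralogy: reads from the block
#' multimap across those loci. Block positions are never mutated, so the
#' block stays shared panel-wide. Names follow HLA nomenclature:
#' `locus*lineage:allele` (e.g. `"L1*03:02"`); the reference allele of each
#' locus is `locus*01:01`.
#'
#' @param n_loci Number of loci.
#' @param alleles_per_locus Alleles per locus (distributed over the
#'   lineages).
#' @param divergence_grid Target divergences in \[0, 0.2\], one lineage per
#'   value; the first must be 0 (the reference lineage).
#' @param root_length Root sequence length in nucleotides.
#' @param sibling_subs Substitutions separating a sibling allele from its
#'   lineage founder.
#' @param paralog_block_length Length of the shared paralogous block (0
#'   disables it).
#' @param paralog_loci Indices of the two loci sharing the block.
#' @param seed Integer seed; the panel is fully deterministic given it.
#' @return A list of class `hla_panel`: `alleles` (tibble with `allele`,
#'   `locus`, `lineage`, `sequence`, `target_divergence`, `divergence`
#'   (realized, vs the locus reference), `is_reference`, plus completeness
#'   bookkeeping), `reference` (tibble `locus`, `allele`), `block_loci`,
#'   `block_positions`.
#' @export
make_synthetic_panel <- function(n_loci = 5L, alleles_per_locus = 12L,
                                 divergence_grid = c(0, 0.02, 0.04, 0.06,
                                                     0.08, 0.10),
                                 root_length = 1500L, sibling_subs = 8L,
                                 paralog_block_length = 200L,
                                 paralog_loci = if (n_loci >= 2)
                                   c(n_loci - 1L, n_loci) else NULL,
                                 seed = 1L) {
  if (any(divergence_grid < 0 | divergence_grid > 0.2)) {
    stop("divergence targets must lie in [0, 0.2]", call. = FALSE)
  }
  if (divergence_grid[1] != 0) {
    stop("the first divergence target must be 0 (reference lineage)",
         call. = FALSE)
  }
  n_lineages <- length(divergence_grid)
  per_lineage <- rep(alleles_per_locus %/% n_lineages, n_lineages) +
    (seq_len(n_lineages) <= alleles_per_locus %% n_lineages)
  if (any(per_lineage == 0)) {
    per_lineage <- per_lineage[per_lineage > 0]
    n_lineages <- length(per_lineage)
  }

  withr::with_seed(seed, {
    block <- if (paralog_block_length > 0 && !is.null(paralog_loci)) {
      rand_dna(paralog_block_length)
    } else NULL
    block_at <- min(601L, root_length - paralog_block_length + 1L)
    block_pos <- if (is.null(block)) integer(0) else
      seq(block_at, block_at + paralog_block_length - 1L)

    rows <- list()
    reference <- list()
    for (li in seq_len(n_loci)) {
      locus <- paste0("L", li)
      root <- rand_dna(root_length)
      has_block <- !is.null(block) && li %in% paralog_loci
      if (has_block) {
        root <- paste0(substr(root, 1, block_at - 1L), block,
                       substr(root, block_at + paralog_block_length,
                              root_length))
      }
      pool <- if (has_block) setdiff(seq_len(root_length), block_pos)
              else seq_len(root_length)
      for (lj in seq_len(n_lineages)) {
        target <- divergence_grid[lj]
        m <- round(target * root_length)
        if (m > length(pool)) {
          stop("divergence target ", target, " unattainable at locus ", locus,
               call. = FALSE)
        }
        founder <- NULL
        founder_pos <- integer(0)
        for (try in 1:10) {
          founder_pos <- sample(pool, m)
          founder <- substitute_at(root, founder_pos)
          d <- divergence(founder, root)
          if (target == 0 || abs(d - target) <= 0.1 * target) break
          if (try == 10) stop("could not realize divergence target ", target,
                              call. = FALSE)
        }
        for (s in seq_len(per_lineage[lj])) {
          if (s == 1) {
            seq_s <- founder
          } else {
            extra <- sample(setdiff(pool, founder_pos), sibling_subs)
            seq_s <- substitute_at(founder, extra)
          }
          name <- sprintf("%s*%02d:%02d", locus, lj, s)
          rows[[length(rows) + 1]] <- tibble::tibble(
            allele = name, locus = locus,
            lineage = sprintf("%s*%02d", locus, lj),
            sequence = seq_s,
            target_divergence = target,
            is_reference = (lj == 1L && s == 1L)
          )
        }
      }
      reference[[length(reference) + 1]] <-
        tibble::tibble(locus = locus, allele = sprintf("%s*01:01", locus))
    }
    alleles <- dplyr::bind_rows(rows)
    reference <- dplyr::bind_rows(reference)
  })

  ref_seq <- stats::setNames(
    alleles$sequence[alleles$is_reference][match(reference$locus,
      alleles$locus[alleles$is_reference])], reference$locus)
  alleles$divergence <- vapply(seq_len(nrow(alleles)), function(i) {
    divergence(alleles$sequence[i], ref_seq[[alleles$locus[i]]])
  }, numeric(1))
  alleles$length <- nchar(alleles$sequence)
  alleles$is_complete <- TRUE
  alleles$source <- "observed"
  alleles$accession <- sprintf("SYN:%05d", seq_len(nrow(alleles)))

  structure(list(alleles = alleles, reference = reference,
                 block_loci = if (is.null(block)) character(0) else
                   paste0("L", paralog_loci),
                 block_positions = block_pos, seed = seed),
            class = "hla_panel")
}

#' @export
print.hla_panel <- function(x, ...) {
  cat("synthetic HLA panel:", length(unique(x$alleles$locus)), "loci,",
      nrow(x$alleles), "alleles, divergence grid",
      paste(sort(unique(x$alleles$target_divergence)), collapse = "/"), "\n")
  invisible(x)
}

#' Random non-HLA background transcripts
#'
#' @param n_transcripts Number of transcripts.
#' @param length Transcript length.
#' @param seed Integer seed.
#' @return A non-HLA [reference_set()] with ids `TX01`, `TX02`, ...
#' @export
make_background_transcripts <- function(n_transcripts = 5L, length = 1500L,
                                        seed = 1L) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_transcripts), function(i) rand_dna(length),
                   character(1))
  })
  reference_set(sprintf("TX%02d", seq_len(n_transcripts)), seqs,
                is_hla = FALSE, locus = NA_character_)
}

#' Reference and supplemented reference sets for a panel
#'
#' The "reference transcriptome" holds the background transcripts plus one
#' allele per locus (the designated reference allele), mirroring a standard
#' annotation that carries a single haplotype. The supplemented set replaces
#' those HLA records with the full panel diversity via
#' [build_supplemented_reference()].
#'
#' @param panel An [make_synthetic_panel()] object.
#' @param background A non-HLA [reference_set()].
#' @return List with `reference` and `supplemented` reference sets.
#' @export
panel_reference_sets <- function(panel, background) {
  ref_alleles <- panel$alleles[panel$alleles$is_reference, ]
  reference <- validate_reference_set(dplyr::bind_rows(
    background[, c("id", "sequence", "is_hla", "locus")],
    tibble::tibble(id = ref_alleles$allele, sequence = ref_alleles$sequence,
                   is_hla = TRUE, locus = ref_alleles$locus)))
  supplemented <- build_supplemented_reference(reference, ref_alleles$allele,
                                               panel$alleles)
  list(reference = reference, supplemented = supplemented)
}

#' Sample truth genotypes from a panel
#'
#' Per sample and locus, a heterozygote is drawn with probability
#' `het_fraction` (two distinct alleles, uniform without replacement),
#' otherwise a homozygote (one allele, duplicated). Deterministic under
#' `seed`.
#'
#' @param panel An [make_synthetic_panel()] object.
#' @param n_samples Number of individuals.
#' @param het_fraction Probability a locus genotype is heterozygous.
#' @param seed Integer seed.
#' @return Tibble `sample`, `locus`, `allele1`, `allele2`, `heterozygous`.
#' @export
sample_genotypes <- function(panel, n_samples, het_fraction = 0.7, seed = 1L) {
  stopifnot(het_fraction >= 0, het_fraction <= 1)
  loci <- unique(panel$alleles$locus)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_samples)) {
      for (l in loci) {
        pool <- panel$alleles$allele[panel$alleles$locus == l]
        het <- length(pool) >= 2 && stats::runif(1) < het_fraction
        a <- if (het) sort(sample(pool, 2)) else rep(sample(pool, 1), 2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample = sprintf("S%02d", i), locus = l,
          allele1 = a[1], allele2 = a[2], heterozygous = het)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Divergence-sweep genotypes
#'
#' One individual per divergence level, homozygous at every locus for that
#' level's lineage founder — the controlled design behind the
#' alignment-success-versus-divergence experiment.
#'
#' @param panel An [make_synthetic_panel()] object.
#' @return Genotype tibble in the [sample_genotypes()] format.
#' @export
sweep_genotypes <- function(panel) {
  grid <- sort(unique(panel$alleles$target_divergence))
  loci <- unique(panel$alleles$locus)
  rows <- list()
  for (j in seq_along(grid)) {
    founders <- panel$alleles[panel$alleles$target_divergence == grid[j] &
                                endsWith(panel$alleles$allele, ":01"), ]
    for (l in loci) {
      a <- founders$allele[founders$locus == l][1]
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = sprintf("D%02d", j), locus = l,
        allele1 = a, allele2 = a, heterozygous = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Draw per-transcript fragment counts for one sample
#'
#' Locus- and transcript-level expression weights are log-normal
#' (`meanlog = 0`, `sdlog = 0.5`); a heterozygous locus splits its weight
#' between the two alleles at `allele_balance`. The `n_fragments` total is
#' then distributed by a single multinomial draw.
#'
#' @param genotype Genotype rows of one sample ([sample_genotypes()] format).
#' @param background Non-HLA [reference_set()].
#' @param n_fragments Library size in fragments.
#' @param allele_balance Expected fraction of a heterozygous locus's
#'   expression on the first allele.
#' @param sdlog Log-normal spread of expression weights.
#' @return Tibble `id`, `locus` (`NA` for background), `count`.
#' @export
sample_fragment_counts <- function(genotype, background, n_fragments = 1e5,
                                   allele_balance = 0.5, sdlog = 0.5) {
  w_locus <- stats::rlnorm(nrow(genotype), 0, sdlog)
  w_tx <- stats::rlnorm(nrow(background), 0, sdlog)
  ids <- character(0); loci <- character(0); w <- numeric(0)
  for (i in seq_len(nrow(genotype))) {
    if (genotype$heterozygous[i]) {
      ids <- c(ids, genotype$allele1[i], genotype$allele2[i])
      loci <- c(loci, rep(genotype$locus[i], 2))
      w <- c(w, w_locus[i] * allele_balance, w_locus[i] * (1 - allele_balance))
    } else {
      ids <- c(ids, genotype$allele1[i])
      loci <- c(loci, genotype$locus[i])
      w <- c(w, w_locus[i])
    }
  }
  ids <- c(ids, background$id)
  loci <- c(loci, rep(NA_character_, nrow(background)))
  w <- c(w, w_tx)
  counts <- as.vector(stats::rmultinom(1, n_fragments, w / sum(w)))
  tibble::tibble(id = ids, locus = loci, count = counts)
}

#' Simulate paired-end reads from per-transcript counts
#'
#' For each fragment of transcript t, a fragment length is drawn from
#' `Normal(frag_mean, frag_sd)` (clamped to \[read length, transcript
#' length\]), the start position is uniform, mate 1 is the fragment's 5' end
#' and mate 2 the reverse complement of its 3' end (FR orientation). Every
#' base is then substituted independently with probability `error_rate` to a
#' uniformly chosen different base. Base qualities are constant. Transcripts
#' shorter than the read length are skipped with a warning.
#'
#' @param counts Tibble `id`, `count` (fragments per transcript).
#' @param sequences Named character vector of transcript sequences.
#' @param read_length Read length in bp.
#' @param frag_mean,frag_sd Fragment length model.
#' @param error_rate Per-base substitution error rate.
#' @return List with `reads1`, `reads2`, `ids` (read names carrying the
#'   source transcript) and `truth` (the realized counts table).
#' @export
simulate_reads <- function(counts, sequences, read_length = 75L,
                           frag_mean = 250, frag_sd = 25,
                           error_rate = 0.005) {
  counts <- counts[counts$count > 0, ]
  too_short <- nchar(sequences[counts$id]) < read_length
  if (any(too_short)) {
    warning("skipping ", sum(too_short),
            " transcript(s) shorter than the read length", call. = FALSE)
    counts <- counts[!too_short, ]
  }
  r1 <- vector("list", nrow(counts))
  r2 <- vector("list", nrow(counts))
  ids <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    tx <- counts$id[i]
    s <- sequences[[tx]]
    L <- nchar(s)
    n <- counts$count[i]
    len <- pmin(pmax(round(stats::rnorm(n, frag_mean, frag_sd)),
                     read_length), L)
    start <- floor(stats::runif(n) * (L - len + 1)) + 1
    m1 <- substring(s, start, start + read_length - 1)
    m2 <- substring(s, start + len - read_length, start + len - 1)
    m2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(m2)))
    r1[[i]] <- m1
    r2[[i]] <- m2
    ids[[i]] <- sprintf("%s|%06d", tx, seq_len(n))
  }
  reads1 <- unlist(r1)
  reads2 <- unlist(r2)
  if (error_rate > 0) {
    reads1 <- add_errors_cpp(reads1, error_rate)
    reads2 <- add_errors_cpp(reads2, error_rate)
  }
  list(reads1 = reads1, reads2 = reads2, ids = unlist(ids), truth = counts)
}

#' Simulate a full sample
#'
#' Draws fragment counts and generates reads for one individual, fully
#' deterministic under `seed`.
#'
#' @param genotype Genotype rows of one sample.
#' @param background Non-HLA [reference_set()].
#' @param sequences Named character vector covering every allele and
#'   background transcript.
#' @param n_fragments Library size.
#' @param seed Integer seed.
#' @inheritParams simulate_reads
#' @inheritParams sample_fragment_counts
#' @return A list of class `simulated_sample`: `sample`, `genotype`,
#'   `counts`, `reads1`, `reads2`, `ids`, and the generation parameters.
#' @export
simulate_sample <- function(genotype, background, sequences,
                            n_fragments = 1e5, seed = 1L, read_length = 75L,
                            frag_mean = 250, frag_sd = 25,
                            error_rate = 0.005, allele_balance = 0.5) {
  withr::with_seed(seed, {
    counts <- sample_fragment_counts(genotype, background,
                                     n_fragments = n_fragments,
                                     allele_balance = allele_balance)
    reads <- simulate_reads(counts, sequences, read_length = read_length,
                            frag_mean = frag_mean, frag_sd = frag_sd,
                            error_rate = error_rate)
  })
  structure(
    list(sample = genotype$sample[1], genotype = genotype,
         counts = reads$truth, reads1 = reads$reads1, reads2 = reads$reads2,
         ids = reads$ids, read_length = read_length, frag_mean = frag_mean,
         frag_sd = frag_sd, error_rate = error_rate, seed = seed),
    class = "simulated_sample")
}

#' Alignment success per locus
#'
#' The ratio of estimated to simulated read counts per locus; loci with no
#' simulated reads are omitted.
#'
#' @param estimated Tibble `locus`, `est_count` (e.g. [locus_counts()]).
#' @param simulated Tibble `locus`, `count` of simulated fragments.
#' @return Tibble `locus`, `estimated`, `simulated`, `success`.
#' @export
alignment_success <- function(estimated, simulated) {
  simulated <- simulated[simulated$count > 0, ]
  est <- stats::setNames(estimated$est_count, estimated$locus)
  e <- as.numeric(est[simulated$locus])
  e[is.na(e)] <- 0
  n_sim <- as.numeric(simulated$count)
  tibble::tibble(locus = simulated$locus, estimated = e,
                 simulated = n_sim, success = e / n_sim)
}

#' Run the simulation evaluation experiment
#'
#' Simulates individuals over a synthetic panel and processes each through
#' up to three arms: `personalized` (two-stage typing followed by
#' personalized-index quantification), `reference_only` (EM quantification
#' against the single-haplotype reference transcriptome), and `unique_only`
#' (unique-read counting against the same reference index, emulating
#' conventional unique-mapping pipelines on the transcriptome). Reports
#' per-locus alignment success as a function of allele divergence to the
#' reference.
#'
#' @param panel,background Optional pre-built panel and background; built
#'   from the generator defaults otherwise.
#' @param n_samples Number of individuals (`random` mode; `sweep` mode uses
#'   one per divergence level).
#' @param n_fragments Fragments per sample.
#' @param het_fraction Heterozygote fraction (`random` mode).
#' @param genotype_mode `"random"` genotypes or the controlled divergence
#'   `"sweep"` (each individual homozygous at one divergence level across
#'   all loci).
#' @param pipelines Subset of `c("personalized", "reference_only",
#'   "unique_only")`.
#' @param read_length,frag_mean,frag_sd,error_rate Read simulator settings.
#' @param k K-mer size for all indexes.
#' @param seed Master seed; all per-sample seeds derive from it.
#' @param n_background,... Passed to [make_background_transcripts()] /
#'   [make_synthetic_panel()].
#' @return A list of class `hla_sim_experiment`: `results` (tidy tibble
#'   `sample`, `locus`, `allele`, `divergence`, `heterozygous`, `pipeline`,
#'   `estimated`, `simulated`, `success`), `genotypes` (truth), `calls`
#'   (typing results when the personalized arm ran), `panel`, `background`.
#' @export
run_simulation_experiment <- function(panel = NULL, background = NULL,
                                      n_samples = 20L, n_fragments = 1e5,
                                      het_fraction = 0.7,
                                      genotype_mode = c("random", "sweep"),
                                      pipelines = c("personalized",
                                                    "reference_only",
                                                    "unique_only"),
                                      read_length = 75L, frag_mean = 250,
                                      frag_sd = 25, error_rate = 0.005,
                                      k = 31L, seed = 1L,
                                      n_background = 5L, ...) {
  genotype_mode <- match.arg(genotype_mode)
  known <- c("personalized", "reference_only", "unique_only")
  if (length(setdiff(pipelines, known)) > 0) {
    stop("unknown pipeline(s): ", paste(setdiff(pipelines, known),
                                        collapse = ", "), call. = FALSE)
  }
  if (is.null(panel)) panel <- make_synthetic_panel(seed = seed, ...)
  if (is.null(background)) {
    background <- make_background_transcripts(n_transcripts = n_background,
                                              seed = seed + 7L)
  }
  refsets <- panel_reference_sets(panel, background)
  idx_full <- build_kmer_index(refsets$supplemented, k = k)
  idx_ref <- build_kmer_index(refsets$reference, k = k)
  eff_ref <- effective_length(idx_ref$ref_lengths, frag_mean)
  ref_locus_map <- reference_locus_map(refsets$reference)
  allele_div <- stats::setNames(panel$alleles$divergence, panel$alleles$allele)
  seqs <- stats::setNames(
    c(panel$alleles$sequence, background$sequence),
    c(panel$alleles$allele, background$id))

  genotypes <- if (genotype_mode == "sweep") sweep_genotypes(panel) else
    sample_genotypes(panel, n_samples, het_fraction = het_fraction,
                     seed = seed)
  samples <- unique(genotypes$sample)
  sample_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max %/% 2,
                                              length(samples)))

  results <- list()
  calls_all <- list()
  for (si in seq_along(samples)) {
    g <- genotypes[genotypes$sample == samples[si], ]
    sim <- simulate_sample(g, background, seqs, n_fragments = n_fragments,
                           seed = sample_seeds[si], read_length = read_length,
                           frag_mean = frag_mean, frag_sd = frag_sd,
                           error_rate = error_rate)
    hla_truth <- sim$counts[!is.na(sim$counts$locus), ]
    sim_locus <- dplyr::summarise(dplyr::group_by(hla_truth, .data$locus),
                                  count = sum(.data$count), .groups = "drop")
    arm_locus_counts <- list()

    if ("personalized" %in% pipelines) {
      calls <- genotype_sample(sim$reads1, sim$reads2, refsets$supplemented,
                               index = idx_full, k = k,
                               mean_fragment = frag_mean)
      calls_all[[samples[si]]] <- calls
      pers <- build_personalized_index(calls, refsets$supplemented)
      ab <- quantify_sample(pers, sim$reads1, sim$reads2, k = k,
                            mean_fragment = frag_mean)
      arm_locus_counts$personalized <-
        locus_counts(ab, reference_locus_map(pers))
    }
    if (any(c("reference_only", "unique_only") %in% pipelines)) {
      aln_ref <- pseudoalign(idx_ref, sim$reads1, sim$reads2)
      if ("reference_only" %in% pipelines) {
        ab_ref <- em_quantify(aln_ref$classes, eff_ref)
        arm_locus_counts$reference_only <- locus_counts(ab_ref, ref_locus_map)
      }
      if ("unique_only" %in% pipelines) {
        uc <- unique_counts(aln_ref$classes, ref_ids = idx_ref$ref_ids)
        uc_tbl <- tibble::tibble(ref_id = names(uc), est_count = as.numeric(uc))
        arm_locus_counts$unique_only <- locus_counts(uc_tbl, ref_locus_map)
      }
    }

    for (arm in names(arm_locus_counts)) {
      succ <- alignment_success(arm_locus_counts[[arm]], sim_locus)
      per_allele <- unique(tibble::tibble(
        locus = rep(g$locus, each = 2),
        allele = as.vector(rbind(g$allele1, g$allele2)),
        heterozygous = rep(g$heterozygous, each = 2)))
      per_allele <- per_allele[per_allele$locus %in% succ$locus, ]
      m <- match(per_allele$locus, succ$locus)
      results[[length(results) + 1]] <- tibble::tibble(
        sample = samples[si], locus = per_allele$locus,
        allele = per_allele$allele,
        divergence = unname(allele_div[per_allele$allele]),
        heterozygous = per_allele$heterozygous,
        pipeline = arm,
        estimated = succ$estimated[m], simulated = succ$simulated[m],
        success = succ$success[m])
    }
  }

  structure(
    list(results = dplyr::bind_rows(results), genotypes = genotypes,
         calls = if (length(calls_all) > 0) calls_all else NULL,
         panel = panel, background = background,
         config = list(n_samples = length(samples),
                       n_fragments = n_fragments, het_fraction = het_fraction,
                       genotype_mode = genotype_mode, pipelines = pipelines,
                       read_length = read_length, frag_mean = frag_mean,
                       frag_sd = frag_sd, error_rate = error_rate, k = k,
                       seed = seed)),
    class = "hla_sim_experiment")
}

#' @export
print.hla_sim_experiment <- function(x, ...) {
  cat("simulation experiment:", x$config$n_samples, "samples x",
      x$config$n_fragments, "fragments;",
      paste(x$config$pipelines, collapse = ", "), "\n")
  print(dplyr::summarise(
    dplyr::group_by(x$results, .data$pipeline),
    mean_success = mean(.data$success), .groups = "drop"))
  invisible(x)
}

#' Typing calls of an experiment as one table
#'
#' @param experiment An [run_simulation_experiment()] result with the
#'   personalized arm.
#' @return Row-bound [genotype_table()] over all samples.
#' @export
experiment_calls_table <- function(experiment) {
  if (is.null(experiment$calls)) {
    stop("experiment did not run the personalized arm", call. = FALSE)
  }
  dplyr::bind_rows(lapply(names(experiment$calls), function(s) {
    genotype_table(experiment$calls[[s]], sample = s)
  }))
}
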