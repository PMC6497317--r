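# hlaquant

Personalized HLA genotyping and allele-level expression quantification
from paired-end RNA-seq.

## Why

The classical HLA genes are the most polymorphic loci in the human genome
and members of a multi-gene family. Quantifying their expression from
RNA-seq against a single reference haplotype is biased: reads from alleles
divergent from the reference fail to map, and reads shared between
paralogous loci (or between alleles of one locus) are ambiguous.
`hlaquant` implements a two-step personalized pipeline for bulk RNA-seq:

1. **In-silico typing.** Reads are pseudoaligned (canonical k-mer index,
   equivalence classes) against a transcriptome whose HLA transcripts are
   replaced by the full known HLA allele diversity (IMGT/HLA-style FASTA
   input, with completion of partially sequenced alleles). Per locus, a
   two-stage decision procedure — top-5 candidates with a 25%
   intra-lineage filter, 15% lineage- and allele-zygosity thresholds, and
   a 1% confirmation re-check after removing the lead allele's reads —
   infers the 1–2 alleles carried.
2. **Personalized quantification.** Reads are re-aligned against an index
   containing only the called alleles plus the unchanged non-HLA
   transcriptome. Multimapped reads are resolved by maximum likelihood:
   with equivalence-class counts *n<sub>c</sub>*, the EM update

   &theta;<sub>t</sub> &larr; &Sigma;<sub>c</sub> n<sub>c</sub>
   (&theta;<sub>t</sub>/&#8467;<sub>t</sub>) / &Sigma;<sub>u&isin;c</sub>
   (&theta;<sub>u</sub>/&#8467;<sub>u</sub>)

   maximizes &Sigma;<sub>c</sub> n<sub>c</sub> log
   &Sigma;<sub>t&isin;c</sub> &theta;<sub>t</sub>/&#8467;<sub>t</sub>
   (effective lengths &#8467;<sub>t</sub> = max(L<sub>t</sub> − &mu; + 1,
   1)), giving estimated counts and TPM per allele. Gene-level expression
   is the sum over the two alleles; allele-specific expression (ASE) is
   the minor allele's fraction of locus expression, in [0, 0.5].

The package also ships the evaluation machinery: a synthetic HLA-like
panel generator (divergence grid, lineage structure, a shared paralogous
block), a paired-end read simulator (fragment length Normal(250, 25),
substitution errors at 0.005), and a three-arm experiment driver
(personalized vs. reference-transcriptome EM vs. unique-read counting)
measuring per-locus alignment success — the ratio of estimated to
simulated read counts — as a function of allele divergence from the
reference.

## Worked example

```r
library(hlaquant)

panel      <- make_synthetic_panel(seed = 11)           # 5 loci x 12 alleles
background <- make_background_transcripts(seed = 12)
refsets    <- panel_reference_sets(panel, background)

genotype <- sample_genotypes(panel, n_samples = 1, het_fraction = 0.7,
                             seed = 13)
seqs <- setNames(c(panel$alleles$sequence, background$sequence),
                 c(panel$alleles$allele, background$id))
sim  <- simulate_sample(genotype, background, seqs, n_fragments = 1e5,
                        seed = 14)

calls <- genotype_sample(sim$reads1, sim$reads2, refsets$supplemented)
calls
#> L1: L1*02:01 (homozygous) [confirmed]
#> L2: L2*05:02 / L2*03:01 [confirmed]
#> L3: L3*06:02 / L3*03:02 [confirmed]
#> L4: L4*04:02 / L4*06:02 [confirmed]
#> L5: L5*01:01 / L5*05:02 [confirmed]
```

Every call matches the simulated truth (locus L1 is a true homozygote).
Quantifying against the personalized index:

```r
pers      <- build_personalized_index(calls, refsets$supplemented)
abundance <- quantify_sample(pers, sim$reads1, sim$reads2)
expr      <- allele_expression(abundance)

gene_level(expr)
#>   sample  locus     tpm est_count
#> 1 sample1 L1     44696.     4467
#> 2 sample1 L2    147426.    14734
#> 3 sample1 L3    180705.    18060
#> 4 sample1 L4    128423.    12835.
#> 5 sample1 L5     62228.     6219.

ase_table(expr)
#>   sample  locus   ase
#> 1 sample1 L2    0.499
#> 2 sample1 L3    0.495
#> 3 sample1 L4    0.496
#> 4 sample1 L5    0.493
```

TPM values are on the whole-transcriptome scale (background transcripts
included; TPM sums to 10^6). The simulated heterozygotes were generated
with balanced allele expression, and the estimated ASE is ~0.5 at every
heterozygous locus; the homozygous locus L1 has no ASE row.

See `vignette("hla-personalized-quantification")` for the model,
thresholds, simulator assumptions, and design decisions.

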