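Package: hlaquant
Title: Personalized HLA Genotyping and Allele-Level Expression from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Genotyping and expression quantification for the highly
    polymorphic HLA genes from paired-end RNA-seq reads. Reads are
    pseudoaligned with a k-mer index built over a reference transcriptome
    in which the generic HLA transcripts are replaced by the full known
    HLA allele diversity; multi-mapping reads are resolved by
    expectation-maximization, HLA genotypes are inferred by a two-stage
    in-silico typing procedure, and expression is re-quantified against a
    personalized index containing only the alleles carried by the
    individual. Includes a paired-end read simulator and an evaluation
    harness for alignment-success and typing-concordance experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    dplyr,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
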