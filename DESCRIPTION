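Package: chipdesign
Title: Design and Evaluation of Custom SNP Genotyping Arrays from Multi-Breed Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate breed-specific SNP genotyping arrays
    from multi-breed whole-genome sequence variants. Implements technical
    suitability filtering (interfering-neighbour windows, read-depth,
    allele-frequency and in-silico conversion-score filters), breed-unique and
    allele-frequency-divergence classification, VEP-style consequence-to-impact
    mapping with reclassification overrides, two-locus linkage disequilibrium
    statistics from unphased genotypes (EM haplotype frequencies, D-prime,
    r-squared and likelihood-based D-prime confidence intervals),
    Gabriel-style confidence-interval haplotype-block calling, an ordered
    ten-category variant selection engine with complete-LD pruning, gap
    filling and probeset accounting, and post-genotyping evaluation
    (confidence masking, call-rate QC, segregation, concordance and residual
    gap analysis). A synthetic multi-breed cohort simulator with
    block-structured linkage disequilibrium makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
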