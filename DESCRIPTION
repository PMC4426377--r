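Package: refbias
Title: Benchmarking NGS Genotype Calls Against Gold-Standard HLA Typings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark SNP genotype calls and allele-frequency
    estimates from next-generation sequencing against Sanger-derived HLA
    typings treated as a gold standard. Expands possibly ambiguous HLA allele
    names into antigen-recognition-site (ARS) exon consensus sequences,
    deconstructs diploid typings into per-site genotypes, compares them with
    VCF calls under an ambiguity-correction rule, computes reference-allele
    frequency errors (FE) and per-gene mean absolute error (MAE), classifies
    and flags unreliable sites across populations, tests the direction of
    frequency deviations with an exact binomial test, and probes reference
    mapping bias with 51-bp flanking-window mismatch statistics compared by
    one-tailed rank-sum tests. A synthetic-data generator with a per-read
    mapping-loss model produces gold and NGS datasets with the same structure
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    readr,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
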