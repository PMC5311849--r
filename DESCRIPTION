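Package: rvburden
Title: Multi-Phenotype Burden Regression for Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Collapses rare variants within genomic regions into a
    per-individual proportion of minor alleles and regresses that
    proportion, by weighted linear "reverse regression", on every
    non-empty combination of user-specified phenotypes. Reports
    likelihood-ratio-test p-values, log-likelihoods, Bayesian
    Information Criterion values and per-phenotype effect estimates
    for each phenotype combination. Reads SNPTEST v2 sample and GEN
    genotype-probability files and plain-text region and identifier
    lists, writes tab-separated result, betas, log and error files,
    and ships a seeded synthetic-data generator for genotype
    probability triplets and correlated phenotypes with known effects
    on the regional burden.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment, GenomicRanges
Imports: methods, stats, utils, S4Vectors, IRanges, MASS
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
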