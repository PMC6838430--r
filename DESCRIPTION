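Package: httex1
Title: HTT Exon-1 Repeat Structure, Somatic CAG Expansion, and Clinical
    Association Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-level genotyping of the glutamine-encoding repeat in
    exon 1 of HTT (codon-cassette decomposition, HGVS-style annotation,
    emulation of fragment-length mis-sizing of atypical alleles),
    quantification of somatic CAG expansion from per-allele read-length
    distributions, individual-specific somatic expansion scores as residuals
    of age-by-repeat-length regressions, and the downstream clinical
    association suite: stratified Cox time-to-onset models with permutation
    p-values for repeat-structure terms, bias-corrected accelerated (BCA)
    bootstrap model comparison, mixed-model longitudinal progression rates,
    least-square means, candidate-SNP association with exact Hardy-Weinberg
    tests, and sample-size-weighted meta-analysis across cohorts. Includes a
    seeded synthetic-data generator that emulates every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    lme4,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    boot,
    emmeans,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
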