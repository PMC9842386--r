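Package: regaudit
Title: Gene-Anchored Audit of GWAS Associations Against Expression and
    Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether GWAS associations at trait-linked
    genes are explained by effects on gene expression. Implements
    pext-based selection of commonly coding variants and COJO-style
    conditioning of summary statistics on them, greedy locus calling with
    proximity enrichment against a resampled random-gene null,
    eQTL discovery under an inflated-test-count Benjamini-Hochberg
    procedure, approximate-Bayes-factor colocalization posteriors
    (PP0-PP4) and eCAVIAR-style CLPP on stepwise single-effect
    fine-mapping posteriors, and activity-by-distance (ABD) scoring of
    histone and DNase chromatin features against gene transcription
    start sites. A synthetic-study generator produces LD-consistent
    paired GWAS/eQTL summary statistics with controllable
    colocalization structure, chromatin tracks, and pext tables so the
    whole pipeline runs and is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
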