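Package: ohnologR
Title: Anatomical Expression Enrichment and Duplicate-Gene Retention After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the retention of duplicate genes (ohnologs) after
    whole-genome duplication in vertebrates. Provides anatomical-ontology
    expression enrichment with classic, elim, and weight decorrelation
    algorithms; phylogenomic classification of ohnologs, singletons, and
    small-scale duplicates from event-annotated gene trees; Akashi's test for
    translational-accuracy selection summarised as a Mantel-Haenszel
    stratified odds ratio (Psi) and Z score; equal-frequency bin regression
    of retention rate on gene covariates; RNA-seq present/absent calling
    against intergenic background; and seed-reproducible synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
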