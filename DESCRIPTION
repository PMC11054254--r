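Package: virotraj
Title: Stage-Wise Gut Virome Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for stage-wise gut-virome analysis from
    viral metagenome contigs: greedy dereplication of contigs into viral
    operational taxonomic units (vOTUs) at ANI/coverage thresholds, coverage
    breadth and TPM abundance normalization, alpha and beta diversity,
    classification of per-vOTU temporal trajectories across three
    developmental stages into six categories by Kruskal-Wallis and Dunn
    post-hoc tests, per-category hypergeometric term enrichment with
    Benjamini-Hochberg q-values, viral auxiliary metabolic gene (vAMG)
    curation from annotation output, and temperate-versus-lytic phage
    abundance contrasts. Includes a seeded synthetic-study generator with
    planted, recoverable structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    vegan,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
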