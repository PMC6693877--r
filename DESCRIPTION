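Package: tabhmc
Title: Paired Bisulfite and TET-Assisted Bisulfite Array Analysis of
    5-Hydroxymethylcytosine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and differential analysis of 5-hydroxymethylcytosine
    (5hmC) and 5-methylcytosine (5mC) from paired bisulfite (BS) and
    TET-assisted bisulfite (TAB) methylation-array channels. Implements
    detection-p quality filtering, exponential-normal (normexp) background
    correction, quantile normalization, constrained maximum-likelihood
    resolution of per-CpG (5mC, 5hmC) levels from the two channels, paired
    moderated t-tests with Bonferroni control for tumor versus adjacent
    tissue, genomic-feature and histone-mark enrichment by one-sided
    Fisher tests, and permutation-based gene-set enrichment with empirical
    p-values. A seeded synthetic-data generator emulates the statistical
    structure of a paired tumor/adjacent TAB-array study so the whole
    pipeline runs and is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
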