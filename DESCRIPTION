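Package: oncowga
Title: Tumor Whole-Genome Interpretation and Real-World Outcome Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling interpretation of paired tumor-normal
    whole-genome sequencing and cohort-level real-world outcome analysis.
    Implements a sequencing quality gate, the five-rule somatic small-variant
    filter cascade (population allele frequency, cohort recurrence, simple
    repeats, noisy indel windows, and a panel-of-normals Fisher exact test on
    the Phred scale), consequence annotation on canonical transcripts, copy
    number gain/loss actionability rules including loss-of-heterozygosity
    scenarios, gene-fusion reading-frame assessment across structural variant
    breakpoints, germline predisposition and pharmacogenomic reporting,
    pangenomic markers (tumor mutational burden, 96-context mutation catalogs,
    nonnegative signature refitting with etiology grouping and mismatch-repair
    classification), linkage of cases to registry and hospital-episode tables
    with stage resolution, and cohort analytics (actionability prevalence,
    copy-number/small-variant co-occurrence testing, and stage-corrected
    survival stratification). A synthetic cohort generator with known ground
    truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    survival,
    pracma,
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
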