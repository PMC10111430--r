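Package: hairpincall
Title: Bisulfite Methylation Calling with Hairpin-Artifact Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Whole-genome bisulfite sequencing (WGBS) methylation calling
    against a spike-in-derived conversion-failure null, with downstream
    screening for false positives caused by DNA secondary structure.
    Per-cytosine calls combine a coverage filter, the Wilson score interval
    on the methylation ratio, and a one-sided binomial test whose success
    probability is the bisulfite conversion-failure rate, with
    multiple-testing correction. Robust sites are intersected across
    replicate methylomes, mapped onto genome-wide palindromic (inverted
    repeat) sequences, and classified as hairpin stem or loop positions.
    Clone-level targeted bisulfite (BSP) statistics, read-depth knockout
    verification, and a seeded synthetic bisulfite-count simulator with
    hairpin-stem protection complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    graphics,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
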