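Package: dielcycle
Title: Paired mRNA-Protein Expression Dynamics over Light-Dark Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired transcript and protein abundance
    timecourses from light-dark synchronized cell populations. Includes
    isotope-ratio peak-to-protein rollup with quality filtering and
    lognormal ratio estimation, strand-specific transcript quantification
    from per-base coverage, detection of 24-hour rhythmicity against
    per-gene AR(1) simulated null distributions with pi0/q-value false
    discovery control, phase/amplitude/lag comparison between expression
    levels, and a ground-truthed synthetic data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    jsonlite,
    withr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
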