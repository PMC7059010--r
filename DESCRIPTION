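Package: cinscna
Title: Somatic Copy Number Alteration Calling for Low-Pass Sequencing of
    Chromosomally Unstable Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidy pipeline for somatic copy number alteration (SCNA)
    analysis of low-pass whole-genome sequencing from chromosomally
    unstable tumour genomes. Simulates ground-truthed tumour/normal binned
    coverage over a mouse-like genome (whole and partial chromosome gains
    and losses, focal amplicons including stepped breakage-fusion-bridge
    profiles, gross rearrangements), normalizes binned counts to a matched
    control as median-centred log2 ratios, segments profiles with a
    from-scratch circular binary segmentation using permutation-based
    split significance, classifies segments into SCNA categories
    (whole/partial chromosome gain or loss, focal amplification or
    deletion, gross chromosomal rearrangement), aggregates cohort
    recurrence including minimal common amplified regions, and implements
    validation-assay statistics: Poisson-corrected digital-PCR copy-ratio
    estimation with delta-method confidence intervals and FISH spot-count
    summaries with a genome-doubling exclusion filter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
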