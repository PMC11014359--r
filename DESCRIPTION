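Package: tailrace
Title: Tail Classification and Censored Length Estimation for 3' RACE-seq
    of mRNA Non-Templated Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted 3' RACE-seq amplicon libraries
    of mRNA 3' ends. Simulates library preparation (UMI-carrying
    preadenylated adapter, sample index, PCR duplication, sequencing
    error), demultiplexes and parses paired reads, anchors templated ends
    on reference amplicons, classifies non-templated additions into
    A-tail, AU-tail, U-tail and no-tail classes, estimates tail lengths
    with explicit right-censoring at the observable window, collapses PCR
    duplicates by unique molecular identifier, stratifies LINE-1 reads by
    subfamily diagnostic nucleotides, and produces per-sample summaries
    with chi-square and Mann-Whitney comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    S4Vectors,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
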