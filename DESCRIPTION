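Package: bescan
Title: BAC-End Sequence Characterization and Comparative Synteny Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome surveys built on BAC-end sequences (BES):
    library-based repeat masking with a seed-and-extend local aligner and a
    self-alignment hit census, microsatellite (SSR) mining with canonical
    motif classes and flank-eligibility filtering, three-step filtration of
    BLAST tabular hits down to unique per-read assignments, paired-end
    macro-/micro-synteny calling against reference genomes with span and
    tail-to-tail orientation rules, and the survey summary statistics
    (sequencing accounting, GC and Q20 metrics, SSR class distributions,
    marker polymorphism rates, per-species synteny tables). A fully seeded
    synthetic-data generator emulates every pipeline input with recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
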