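Package: castworks
Title: Host-Factor Screens and Insertion-Outcome Analysis for CRISPR-Associated Transposases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational workflows around bacterial genome editing with
    CRISPR-associated transposases (CASTs): differential RB-TnSeq gene-fitness
    screening with a two-screen consistency rule, long-read profiling of
    integration outcomes (on-target rate, orientation, insertion offset,
    cointegrate frequency), safe-site and guide design with PAM scanning and
    seed-region off-target scoring, and CFU-based editing-efficiency statistics
    from serial-dilution spot plates. Includes synthetic-data generators with
    planted ground truth for parameter-recovery testing of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
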