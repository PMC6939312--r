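Package: abtscore
Title: Charge-Tract Scoring of Intrinsically Disordered Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies intrinsically disordered regions (IDRs) from per-residue
    disorder propensity tracks and scores the density of contiguous acidic and
    basic tracts within them. Computes windowed net-charge-per-residue (NCPR)
    profiles, detects sign-constant charged tracts and their areas, evaluates
    the Das-Pappu kappa charge-segregation parameter with an exact
    dynamic-programming maximization, and combines these into per-IDR scores, a
    per-protein ABTscore and a length-normalized ABTdensity. Includes
    proteome-scale batch scoring, percentile stratification into four groups,
    accession-list export for downstream enrichment tools, and a synthetic
    sequence/disorder-track generator with controlled charge architectures for
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
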