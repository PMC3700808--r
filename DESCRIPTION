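Package: spliceshield
Title: Statistical Analysis of Alternative Splicing at Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether alternative splicing avoids partial removal
    of protein-protein interaction sites. Extracts interface residues from
    structures with a van der Waals distance criterion, encodes splice
    isoforms as two-bit masks over the canonical protein from CDS genomic
    coordinates, generates randomized-splicing decoy isoforms by Poisson
    pulsing of missing and non-missing stretches, and compares real versus
    randomized interface removal with stratified Cochran-Mantel-Haenszel
    chi-square tests. Includes interface redundancy reduction by overlap
    clustering, hot-spot independence testing, selectivity scoring with
    hypergeometric term enrichment, and a synthetic-data generator with a
    tunable splicing bias for end-to-end validation.
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
    ggplot2,
    jsonlite,
    generics,
    igraph,
    bio3d,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
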