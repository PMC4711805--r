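Package: islandshift
Title: Genomic Island Prediction by Mean-Shift Clustering of Nucleotide
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts genomic islands (horizontally transferred regions) in
    complete bacterial genomes by partitioning the genome into fixed-length
    windows, representing each window by its (A,T,C,G) count vector, and
    clustering the windows with a mean-shift mode-seeking procedure whose
    kernel bandwidth is tuned automatically by an artificial-fragment
    insertion heuristic: compositionally deviant fragments drawn from donor
    genomes are inserted and the bandwidth is decreased until every fragment
    separates into its own cluster. Low-mass clusters (at most 200 kb of
    window length by default) are reported as candidate genomic islands.
    Includes a cumulative G+C profile for visualisation and a synthetic
    genome generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
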