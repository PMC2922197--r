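Package: pepspectra
Title: Enzymatic and Taxonomic Spectra from Short Metagenomic Reads via
    Specific Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly-free functional and taxonomic profiling of short
    metagenomic reads (50-200 nt). Each read is translated into six
    pseudo-peptides (three frames on both strands) which are searched for
    exact occurrences of Specific Peptides, short amino-acid motifs (>= 7
    residues) diagnostic of Enzyme Commission (EC) categories. Hit counts
    are converted to predicted enzyme-gene numbers through calibration
    factors trained on annotated genomes, yielding an enzymatic spectrum;
    taxon-specific peptides from single-copy aminoacyl-tRNA synthetases
    (the S61 set) give a coarse taxonomic mixture. Includes a seeded
    synthetic-genome fixture generator, an Aho-Corasick multi-pattern
    matcher, read-simulation calibration, chi-square fit diagnostics,
    anomaly flagging, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
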