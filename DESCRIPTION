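Package: transelect
Title: Cross-Species Signatures of Selection on Bacterial Translation Machinery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how selection for translation efficiency
    shapes bacterial translation machinery across species with different
    generation times. Parses annotated genomes (GenBank flat files), extracts
    coding, tRNA and rRNA features, computes start/stop codon usage, codon
    adaptation (index of translation efficiency and its HEG-vs-REST
    difference DITE), the effective number of anticodons in the tRNA gene
    pool, Shine-Dalgarno signals (positional frequencies, position weight
    matrices, distance to start), and sliding-window minimum-folding-energy
    profiles around translation signals. Includes the cross-species
    statistical layer (OLS with class dummies and interactions, midrank
    transforms and rank regressions, floor-exponential fits of rRNA operon
    and tRNA gene counts on ranked generation time) and a synthetic genome
    panel generator with a ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    readr,
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    broom
Config/testthat/edition: 3
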