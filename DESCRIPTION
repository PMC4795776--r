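Package: tmvar
Title: Topology-Aware Analysis of Missense Variants in Human
    Transmembrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps missense genetic variants (disease-associated mutations
    and natural polymorphisms) onto the membrane topology of transmembrane
    proteins and contrasts their amino-acid substitution spectra by
    topological region. Provides region-stratified 20x20 substitution
    matrices with bootstrap dispersion estimates, a random-position
    permutation null with per-cell z-scores, polarity-class (polar,
    non-polar, charged) aggregation, predictive values for frequent
    transmembrane substitutions, normalized distance-from-helix-center
    profiles, and variant density profiles along the membrane normal of
    3D structures. Includes a configurable synthetic proteome, variant and
    structure generator so the whole pipeline is testable without external
    downloads, plus readers for variant tables, topology annotations,
    FASTA, BED and minimal PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
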