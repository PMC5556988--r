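Package: tepaleo
Title: Transposon Paleontology: Mining, Annotating and Dating DNA Transposon Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of Tc1-mariner DNA
    transposon families in genome assemblies. Homologous copies are mined
    with a self-contained seed-and-extend nucleotide search (Karlin-Altschul
    E-values), structurally annotated for terminal inverted repeats,
    target-site duplications and transposase open reading frames, and
    collapsed into per-species majority consensus elements. Copy ages are
    estimated from Kimura two-parameter divergence via T = k/(2r), and
    horizontal transposon transfer is tested by comparing element consensus
    divergence against the divergence distribution of single-copy host
    orthologs. A sequence-evolution simulator with known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
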