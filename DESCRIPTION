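Package: cretrace
Title: Multi-Evidence Localisation of Cis-Regulatory Elements from
    Population Genomic, Chromatin and Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for localising cis-regulatory
    elements (CREs) that control a discrete phenotype, built around the
    evidence chain used to map wing-pattern switch loci in Heliconius
    butterflies: sliding-window topology weighting of phenotype
    hypotheses over phased haplotypes, chromatin-accessibility peak
    calling and peak/association intersection, phenotype-concordant
    read-depth drop scanning for structural variants and transposable
    element insertions, virtual-4C contact-enrichment testing against an
    empirical distance-decay background, affine-gap consensus-sequence
    alignment with indel calling, and Fourier estimation of scale-ridge
    spacing. A synthetic-data generator with recorded ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    S4Vectors,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
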