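Package: mpradisect
Title: Single-Nucleotide Dissection of Enhancers by Massively Parallel Reporter Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing saturation-mutagenesis massively parallel
    reporter assays (MPRA) of enhancers, including exonic enhancers. Covers
    the full computational workflow: simulation of doped-oligonucleotide
    haplotype libraries with planted effect landscapes, tag counting and
    aliquot-presence filtering of RNA barcode reads, subassembly
    reconstruction of tagged haplotypes from fragment reads, per-position
    univariate and per-substitution trivariate effect-size regression on
    aliquot counts, sliding-window F-statistic profiles, fold-change
    classification with coding-consequence annotation, lag-distance
    permutation tests for spatial clustering of effects, position weight
    matrix (PSSM) scoring of variant impact on transcription factor binding
    sites, and standardized cross-condition profile comparison with loess
    smoothing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
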