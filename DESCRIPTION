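Package: srnatlas
Title: Small RNA Expression Atlas Construction from Plant Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for building a plant microRNA expression atlas
    from small RNA sequencing libraries: adapter trimming and 18-34 nt size
    selection, unique-tag collapsing, exact genome mapping with structural-RNA
    exclusion, transcripts-per-five-million (TP5M) normalization, hairpin
    folding by weighted base-pair maximization, dominant-isoform and
    miRNA-star duplex analysis with 2-nt 3' overhang geometry, novel miRNA
    candidate validation, dual-replicate expression calls with organ
    specificity classification, correlation-distance clustering with optimal
    leaf ordering, principal component analysis, and plant-style miRNA target
    site scoring filtered by expression anti-correlation. Includes a fully
    specified synthetic data generator (genome, hairpin loci, siRNA clusters,
    structural decoys, organ-by-stage read libraries, coupled mRNA atlas) so
    the whole pipeline is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    stringi,
    rlang,
    ggplot2,
    generics,
    withr,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readr
Config/testthat/edition: 3
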