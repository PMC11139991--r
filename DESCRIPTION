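Package: sporeclust
Title: Taxonomically Constrained OTU Clustering and Validation for Airborne
    Fungal Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-denoising toolkit for airborne fungal ITS2 metabarcoding
    surveys. Collapses end-gap duplicate amplicon sequence variants (ASVs),
    builds sparse pairwise global-alignment dissimilarity matrices, optimizes
    per-taxon single-linkage clustering thresholds by multi-class F-measure
    against a reference database, and clusters ASVs into species-level OTUs
    by a three-stage (cluster-core, closed-reference, de novo pseudotaxon)
    procedure nested across taxonomic ranks. Also provides kingdom-level
    filtering against annotated references, spike-in based semi-quantitative
    DNA quantification, sequencing-depth and negative-control diagnostics
    with analytic rarefaction, a distance-weighted occurrence null model for
    validating taxonomic classifications against occurrence databases, and
    seeded synthetic-data generators that emulate every input of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
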