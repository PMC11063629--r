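Package: tumorevo
Title: Copy-Number Inference from Single-Cell Expression and Mutation-Time
    Reconstruction of Tumor Evolution
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for reconstructing chromosome-arm copy-number
    evolution in tumors. Infers copy-number aberrations from single-cell
    RNA-seq counts (trimmed-mean normalization, genome-ordered expression
    bins, smoothed winsorized Z-scores, Louvain communities on a KNN graph,
    meta-cell construction and a three-state Gaussian HMM with Wilcoxon
    segment testing), times copy-number gains and whole-genome doubling in
    mutation time from clonal SNV multiplicities via MCMC, aggregates event
    order across a cohort with a league model, and applies presence-pattern
    heuristics for clone assignment and most-recent-common-ancestor
    allele-specific copy-number reconstruction. Ships a synthetic-data
    generator with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
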