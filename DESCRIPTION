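Package: psifold
Title: Predicting Splice-Site Variant Effects on Exon Inclusion from
    Probing-Guided RNA Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative prediction of the effect of single-nucleotide
    variants on alternative splicing outcome (percent spliced in, PSI) at a
    5' splice site.  Combines chemical-probing-guided RNA secondary
    structure ensembles -- via a self-contained nearest-neighbor folding
    engine with reactivity pseudo-energies, partition function, base-pair
    probabilities and stochastic Boltzmann sampling -- with unfolding free
    energies of spliceosome footprint regions and splicing-regulatory-
    element motif strength changes, feeding a category-gated beta
    regression of PSI on structural and sequence features.  Includes a
    synthetic-data generator emulating the study design (junction hairpin
    sequences, context-dependent reactivities, mutation panels with
    Beta-distributed PSI) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    bio3d,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
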