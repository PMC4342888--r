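Package: hbmarkers
Title: Protein Marker Discovery for Honey Bee Hygienic Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a quantitative-proteomics
    biomarker discovery pipeline for honey bee (Apis mellifera) hygienic
    behavior. Provides a constrained randomized incomplete block design for
    triplex isotope-labeled samples, peptide-spectrum-match filtering by
    target-decoy false discovery rate, parsimony protein inference, robust
    normalization of block-structured protein quantification matrices,
    per-protein mixed-model association of expression with colony phenotypes
    under Benjamini-Hochberg control, multi-dataset marker ranking combining
    statistical, biological and heritability evidence, and estimation of
    fluorescence competitive-binding constants (probe K_d, IC50, competitor
    K_d). A synthetic-data suite emulates the statistical structure of the
    field study (colony phenotypes, partial diallel pedigrees, block-level
    missingness, decoy score mixtures, binding equilibria) so that every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
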