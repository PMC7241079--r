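Package: pmnet
Title: Phenotype-Supervised Protein-Metabolite Network Discovery via Sparse Multiple Canonical Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates a proteomic and a metabolomic abundance matrix with a
    continuous phenotype to discover phenotype-associated protein-metabolite
    networks. Implements sparse multiple canonical correlation analysis (SmCCA)
    with a phenotype scaling constant, penalty selection by k-fold
    cross-validation, a consensus feature-similarity matrix averaged over
    feature subsamples, hierarchical module extraction with edge trimming,
    first-principal-component network summaries, covariate-adjustment
    sensitivity comparison via Fisher's exact node overlap, spirometric (GOLD)
    and emphysema-severity grading, and subgroup analysis by ANOVA with Tukey's
    HSD. Includes metabolomics preprocessing (run-day median normalization,
    outlier-subject removal, missingness filtering, k-nearest-neighbor
    imputation, log transformation and standardization, covariate
    residualization) and a seeded synthetic multi-omics generator with planted
    latent signal for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
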