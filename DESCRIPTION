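Package: limbicscreen
Title: Amygdala Seed Functional Connectivity Screening of Bipolar Versus
    Unipolar Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Seed-based resting-state functional connectivity analysis for
    separating bipolar from unipolar depression. Builds Fisher z-transformed
    amygdala-seed correlation maps from preprocessed BOLD runs, performs
    region-based feature selection (tree-ensemble impurity scores aggregated
    over atlas regions and admitted sequentially by a Mann-Whitney rule),
    trains and evaluates a cross-validated linear max-margin classifier with
    permutation significance, and provides the accompanying group statistics
    (ANOVA, Kruskal-Wallis, chi-square, exact tests, variance-dependent
    post-hocs, Pearson correlations with Benjamini-Hochberg correction).
    Includes a synthetic cohort generator emulating the assumed data
    structure so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    car,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
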