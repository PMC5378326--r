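Package: deltol
Title: Predicting Tolerance to Single Amino-Acid Deletions from Protein
    Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict whether a single amino-acid deletion in a
    protein is functionally tolerated from per-residue structural
    properties: side-chain weighted contact number (WCN), relative solvent
    accessibility (RSA), secondary-structure category, and a mean
    protein-design score. Computes side-chain WCN and Shrake-Rupley
    solvent-accessible surface area directly from PDB coordinates,
    assembles per-mutant feature tables, and evaluates logistic-regression
    and radial-kernel support-vector-machine classifiers over all predictor
    subsets by repeated 10-fold cross-validated pooled-ROC AUC, with group
    comparisons (Welch t-tests, chi-squared contingency) and principal
    component analysis of the predictors. Includes seeded synthetic-data
    generators (pseudo-structures, feature tables with known ground truth,
    binormal score sets) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
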