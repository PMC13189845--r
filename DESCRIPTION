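Package: habitatomics
Title: Habitat Radiomics for Multiparametric MRI Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates co-registered multiparametric MRI lesion phantoms
    (T1-weighted, T2-weighted and apparent diffusion coefficient channels)
    with planted intratumoral subregions, partitions lesions into habitats by
    voxel-wise k-means with Calinski-Harabasz selection of the cluster
    number, extracts a 107-feature IBSI-style radiomic set per region and
    sequence, reduces features by reproducibility (ICC), relevance (Welch t,
    mRMR), redundancy (Pearson) and sparsity (cross-validated LASSO), and
    fits and evaluates logistic classifiers with DeLong confidence intervals
    and paired tests, calibration curves, decision-curve analysis and exact
    linear SHAP attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    RNifti,
    yaml,
    jsonlite,
    withr,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust
Config/testthat/edition: 3
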