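Package: phenoheight
Title: UAV Multisensor Plant-Height Phenotyping and Genome-Wide Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses UAV-based plant-height field trials at desk
    scale. Generates synthetic terrain, canopy point clouds, surface rasters,
    genotypes and replicated phenotypes with known ground truth; builds digital
    terrain, surface and canopy height models from classified point clouds;
    extracts per-plot heights by percentile differencing and zonal statistics;
    calibrates extracted heights against manual measurements with polynomial
    and machine-learning regressors scored by R2, MAE, MSE, RMSE, RMSLE and
    MAPE; clusters accession growth trajectories with k-means and selects the
    cluster count by the gap statistic; and runs a kinship-corrected
    mixed-model association scan (EMMAX approximation) with peak merging,
    gene lookup and haplotype comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    FNN,
    interp,
    mgcv,
    MASS,
    rpart,
    randomForest,
    ranger,
    xgboost,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
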