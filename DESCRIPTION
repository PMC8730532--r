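Package: herimap
Title: Voxelwise SNP Heritability Mapping and Data-Driven Extraction of
    Highly Heritable Brain Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates SNP-based heritability for voxel-level brain imaging
    quantitative traits with a single-component GREML (AI-REML) linear mixed
    model on a genetic relationship matrix, then extracts spatially connected
    regions of high (or low) heritability from the smoothed significance map
    and re-estimates heritability for the region-averaged traits.  Includes
    genotype quality control (MAF, call rate, exact Hardy-Weinberg test,
    per-sample missingness), GRM construction with population-structure
    principal components, PLINK and NIfTI input/output, an atlas comparison
    arm, and a synthetic-data generator with known ground-truth heritability
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
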