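Package: alpsindex
Title: Diffusion-Tensor ALPS Indices and Glymphatic Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the diffusion-tensor image analysis along the
    perivascular space (DTI-ALPS) index of glymphatic function from
    diffusion-weighted MRI, from gradient-table handling and log-linear
    tensor fitting through ROI-based directional diffusivities to
    left/right ALPS indices and placement-reliability ICCs. Includes a
    synthetic-data layer (DWI phantoms with known ground-truth tensors,
    simulated patient/control cohorts with calibrated clinical scores),
    cohort-level statistics (normality-gated two-sample tests, effect
    sizes, one-tailed correlations, standardized multiple regression),
    and data-driven patient subgrouping by Ward hierarchical clustering
    with Calinski-Harabasz model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
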