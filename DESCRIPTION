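Package: mritype
Title: Rules-Based Tissuetype Segmentation and Volumetrics for Multiparametric Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise classification of co-registered multiparametric brain
    MRI (T1w, T1wCE, T2w, FLAIR, and optionally ADC) into nine tissuetypes
    (gray matter, white matter, fluid, blood vessel, contrast-enhancing
    tumor, two edema subclasses, hemorrhage) using an explainable decision
    tree over calibrated intensities. Includes two-point reference-tissue
    intensity calibration, apparent diffusion coefficient mapping from
    two-b-value diffusion-weighted imaging, abnormal-VOI construction and
    intratumoral volumetrics, a longitudinal time-to-progression linear
    model with exhaustive-subset selection by cross-validated AIC, and a
    digital brain phantom generator with ground-truth labels for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
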