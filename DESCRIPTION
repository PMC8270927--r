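Package: plaquefusion
Title: Quantitative Carotid Plaque Composition and FDG-PET Inflammation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline linking carotid atherosclerotic plaque composition to
    plaque inflammation. Plaque composition is quantified from 4-point Dixon
    magnitude MRI as voxel-wise fat fraction (a proxy for lipid-rich necrotic
    core) and R2* relaxation rate (a proxy for intraplaque hemorrhage);
    inflammation is quantified from 18F-FDG PET as standardized uptake values
    and the target-to-blood-pool ratio (TBR). The package provides a digital
    carotid-plaque phantom with known ground truth, voxel-wise Dixon signal
    model inversion, mutual-information similarity registration with a
    (1+1)-evolutionary optimizer, landmark-based slice correspondence,
    mask-restricted neighbour-averaged ROI sampling, SUV/TBR quantification,
    and Pearson correlation statistics with permutation cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
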