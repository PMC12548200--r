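Package: vqpipe
Title: Regional Pulmonary Perfusion and Ventilation from Dual-Energy and
    Static CT with Microsphere Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phantom pipeline for ventilation/perfusion imaging of the
    lung. Implements two-material (water/iodine) decomposition of paired
    low/high-energy CT volumes into virtual non-contrast and iodine
    enhancement images under a fixed iodine ratio; regional perfused
    pulmonary blood volume maps normalised over the lung parenchyma;
    ventilation maps from registered end-expiratory and end-inspiratory
    scans via the Jacobian-weighted gas-fraction difference; processing of
    fluorescence-labelled microsphere cube tables into regional blood-flow
    fractions; and the agreement battery (regression, Bland-Altman,
    change-direction concordance, stratified reporting) used to compare the
    two perfusion surrogates. A synthetic thorax phantom with known
    ventilation and perfusion ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
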