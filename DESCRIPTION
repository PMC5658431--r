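Package: adcrepeat
Title: Measurement-Uncertainty Modelling for ADC Test-Retest Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the repeatability of mean apparent diffusion
    coefficient (ADC) measurements from diffusion-weighted MRI test-retest
    studies.  Provides per-lesion repeatability as symmetric percent change,
    a three-parameter measurement-error model (histogram-width term,
    fixed fitting error, systematic scanner error) fitted by maximum
    likelihood, chi-squared goodness of fit, standardisation of observed
    repeatability against per-ROI predicted uncertainty, and look-up charts
    of uncertainty versus ROI size and ADC histogram width.  Also includes
    voxel-wise mono-exponential ADC estimation with Rician noise-floor
    correction, ROI histogram summaries, a synthetic test-retest cohort and
    DWI phantom generator, and an end-to-end pipeline with figure and
    manifest outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
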