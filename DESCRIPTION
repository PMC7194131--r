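Package: ecgimap
Title: Non-Invasive Electrocardiographic Imaging of Ventricular Activation
    and Voltage Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs unipolar heart-surface electrograms from
    body-surface potential maps by a boundary-element forward model and
    Tikhonov-regularized inverse solution, extracts local activation times
    (steepest negative dV/dt relative to QRS onset) and peak-to-peak
    voltages, aggregates both into AHA 17-segment dispersion summaries, and
    compares patient groups with a heteroscedastic Wald chi-squared test
    (James's approximation), Welch's ANOVA and the Kruskal-Wallis test. A
    synthetic-data module builds biventricular heart and torso meshes, a
    128-electrode array, and four-group cohorts (healthy, post-infarction
    with and without ventricular tachycardia, hypertrophic cardiomyopathy)
    with realistic activation- and voltage-dispersion structure, so the full
    pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
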