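Package: plasmapls
Title: Postmortem Interval Estimation from ATR-FTIR Plasma Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics toolkit for estimating the postmortem interval (PMI)
    from attenuated total reflectance Fourier-transform infrared (ATR-FTIR)
    spectra of blood plasma. Implements spectral preprocessing (standard normal
    variate and Savitzky-Golay second derivatives), PLS1 regression with
    leave-one-out cross-validation and a 5 percent-improvement latent-variable
    rule, variable importance in projection (VIP) scores, outlier screening by
    leverage, Q-residuals and Studentized y-residuals, replicated genetic-
    algorithm wavelength selection (GA-PLS) with selection-frequency
    aggregation, and cosine-squared spectral similarity profiling with one-way
    ANOVA and post hoc testing. Includes a synthetic-data generator that
    emulates postmortem redistribution as a saturating two-endmember spectral
    mixture, so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
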