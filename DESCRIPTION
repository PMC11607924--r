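Package: mixcal
Title: Multivariate Calibration of Severely Overlapped UV/Vis Drug Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for resolving ternary drug mixtures
    (pioglitazone, alogliptin, glimepiride) from overlapped UV/Vis absorbance
    spectra. Provides a cyclic multilevel multifactor calibration design,
    wavelength-band selection, spectral preprocessing (mean centering,
    autoscaling, SNV, MSC, orthogonal signal correction), SIMPLS partial
    least squares with leave-one-out latent-variable selection, score
    compression, gradient-boosted regression trees with exact greedy splits,
    nu-SVR and single-hidden-layer neural-network adapters, recovery/RMSEP/RPD
    evaluation, and a synthetic-spectra generator emulating Beer-Lambert
    mixtures with saturation non-linearity, scatter, drift and noise.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
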