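Package: nirscreen
Title: Near-Infrared Spectral Screening of Falsified and Substandard Medicines
Version: 0.1.0
Authors@R: person("Field", "Screening", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric screening of tablet-form medicines from handheld
    diffuse-reflectance near-infrared spectra (740-1060 nm). Implements
    Savitzky-Golay smoothing and second-derivative preprocessing, a
    Mahalanobis-distance spectral library-matching classifier for detecting
    falsified products, NIPALS partial least squares regression with
    leave-one-out cross-validation for quantifying stated active
    pharmaceutical ingredient content, and tolerance-band classification of
    substandard products. Includes a synthetic spectra generator (Beer-Lambert
    additive Gaussian band model with batch and scan noise) so the full
    pipeline is testable without instrument data, plus stable CSV/JSON
    on-disk formats and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
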