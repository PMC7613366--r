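Package: vitispec
Title: Hyperspectral Estimation of Heavy-Metal Content in Grapevine Foliage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating heavy-metal (Cu, Zn, Pb, Cr, Cd) content in
    grapevine leaves from full-range (350-2500 nm) reflectance spectra.
    Provides a spectral data model with wavelength-grid handling and
    region classification, a registry of 32 vegetation spectral indices,
    min-max scaling and stratified train/test splitting, PLS1 (NIPALS)
    feature selection by maximum factor loading per component with
    cross-validated component counts, forward-selection multiple linear
    regression with Durbin-Watson and variance-inflation diagnostics,
    grid-tuned epsilon support vector regression, and a synthetic
    stress-experiment generator that reproduces the pot/leaf design of a
    controlled heavy-metal dosing experiment so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    car,
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
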