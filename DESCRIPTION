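Package: pcctherm
Title: Photon-Counting CT Thermometry via Material Decomposition and Neural Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for X-ray computed-tomography thermometry with
    photon-counting detectors. Simulates diverging-beam projections of a
    liquid phantom, extracts spectral linear attenuation coefficients from
    empty/filled projection-profile differences with a weak-perspective
    magnification correction, decomposes measured spectra into base-material
    volume fractions under a sum-to-one constraint, and predicts temperature
    with a small fully connected regressor trained on base-material thermal
    series, including Monte-Carlo confidence intervals. A synthetic-data
    generator reproduces the statistical structure of base- and test-material
    measurements so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    zoo,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
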