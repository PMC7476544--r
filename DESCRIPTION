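Package: raytox
Title: Mixture Toxicity Response-Surface Analysis for Binary Quantal
    Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing binary-mixture acute toxicity bioassays
    run on a toxic-unit ray design. Fits three-parameter log-logistic
    dose-response curves to quantal (immobilization) data, builds
    concentration-addition (Loewe) and independent-action (Bliss)
    reference response surfaces, extends both with
    synergism/antagonism, dose-ratio and dose-level deviation
    functions, fits all nested models simultaneously by least squares
    and compares them with likelihood-ratio chi-squared tests. Includes
    a seeded synthetic bioassay generator reproducing the ray
    experimental design, isobole contour extraction, bootstrap
    confidence intervals for EC50s, and CSV/JSON readers and writers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
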