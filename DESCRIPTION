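Package: pulseoxmc
Title: Monte Carlo Modelling of Skin Pigmentation Effects in Reflectance Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photon-packet Monte Carlo simulation of light transport through a
    layered finger model for reflectance photoplethysmography, with epidermal
    melanin and dermal blood absorption composed from chromophore volume
    fractions. Reduces simulated systolic and diastolic reflectance at 660 nm
    and 940 nm to AC/DC components, perfusion indices and the ratio of ratios,
    fits linear oxygen-saturation calibration curves for light, moderate and
    dark skin, derives skin-type correction factors, and quantifies the bias
    and root-mean-square error between transmittance- and reflectance-mode
    calibration algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
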