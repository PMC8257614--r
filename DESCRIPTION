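Package: pricklemap
Title: Spatial Patterning of Prickles on Plant Stems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying and modelling the spatial pattern of
    prickles on plant stems. Converts raw per-stem measurements (angle,
    height) into leaf-relative coordinates (phi, h) using the phyllotaxis
    spline, evaluates an inhibitor-field model in which leaf primordia
    secrete a diffusible inhibitor whose angular footprint follows a von
    Mises profile, and fits the five model parameters to an observed
    prickle density (2D kernel density estimate) by constrained multistart
    BFGS maximising Pearson correlation. A synthetic-stem generator with
    spiral phyllotaxis, divergence-angle noise and a hard-core minimum
    prickle spacing makes the whole pipeline testable without measured
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
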