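Package: iliacshear
Title: Reduced-Order Venous Hemodynamics and Shear-Rate Metrics for Iliac
    Vein Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparative hemodynamic analysis of iliac vein
    compression syndrome (May-Thurner syndrome) at desk scale. Provides a
    synthetic virtual-patient generator for bilateral iliac venous trees
    with a parameterized left common iliac vein stenosis, a Carreau-Yasuda
    shear-thinning rheology layer, a quasi-steady generalized-Poiseuille
    network solver coupled to a three-element (RCR) Windkessel outflow,
    stenosis-defined control-volume shear-rate metrics including the
    LCIV/RCIV shear-rate ratio, an ultrasound-style calibration loop, and
    a case-control statistics and reporting layer with a bundled reference
    cohort of published per-patient metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
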