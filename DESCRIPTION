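Package: vaporCUE
Title: Microbial Growth and Carbon Use Efficiency from 18O Water-Vapor
    Equilibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies soil microbial growth, respiration and carbon use
    efficiency (CUE) from 18O incorporation into genomic DNA when the
    isotope label is delivered by water-vapor equilibration rather than
    liquid water addition. Provides isotope pool mixing mass balance,
    cryodistillation calibration, negative-exponential equilibration
    kinetics (fitting, prediction, closed-form time averaging, and an
    indirect soil-water model built from external-pool measurements),
    headspace CO2 respiration and 18O-DNA growth calculus, and a seeded
    two-pool exchange / rewetting (Birch effect) experiment simulator
    with known ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
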