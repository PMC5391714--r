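Package: windpollen
Title: Pollen-Mediated Gene Flow Frequencies for Wind-Pollinated Plants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic calculator for pollen-mediated gene flow (PMGF)
    frequencies in wind-pollinated plants. Builds a mechanistic pollen
    dispersal kernel (inverse-Gaussian / WALD family) from pollen diameter,
    pollen release height and wind speed, combines it with a donor/recipient
    pollen-competition model driven by outcrossing rate and crossability, and
    returns gene-flow frequency at any distance, frequency-decline curves and
    threshold-based isolation distances. Ships published rice, wheat and
    maize case-study parameter sets as presets and a command-line interface
    for field use.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
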