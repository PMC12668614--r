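Package: planktosink
Title: Composition-Based Modelling of Phytoplankton Gravitational Sinking
Version: 0.1.0
Authors@R:
    person("planktosink", "developers", email = "planktosink@example.org",
           role = c("aut", "cre"))
Description: Links the macromolecular composition of unicellular
    phytoplankton (water, protein, lipid, carbohydrate and other contents)
    to cell density, volume and Stokes-law gravitational sinking velocity.
    Provides simulation sweeps over molecular components with buoyancy
    reversal thresholds, first-order Taylor decompositions attributing
    sinking changes to biophysical (density/volume) or molecular
    (water/dry-content) factors, inference of population biophysics from
    single-cell buoyant mass and volume measurements including the
    dual-fluid (H2O/D2O) dry-content solver, Peclet and Reynolds transport
    numbers, replicate-level hypothesis testing, a synthetic measurement
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
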