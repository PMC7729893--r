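Package: mangrovehm
Title: Gap-Model Growth of Mangrove Stands Under Heavy-Metal Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the growth of planted Rhizophora apiculata
    stands along gradients of pore-water salinity, tree density, ground
    elevation and heavy-metal pollution. Implements a Botkin-type diameter
    growth equation with multiplicative environmental response functions
    (including a hormetic dose-response for root metal burden), extraction of
    lifetime growth rates from plot inventories, nonlinear estimation of the
    response-function parameters, enrichment-factor geochemistry for
    soil/root/leaf metal surveys, and a raster scenario simulator that
    projects stand trunk biomass under alternative chromium loads. Ships the
    11-site Can Gio (Vietnam) survey tables as fixtures and synthetic-data
    generators emulating the full 208-plot inventory and its input rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    graphics,
    tools,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
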