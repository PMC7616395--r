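Package: ploidysim
Title: Individual-Based Simulation of Autotetraploid Establishment in
    Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A spatially explicit, individual-based consumer-nutrient
    simulator of competition between diploid and autotetraploid plants.
    Individuals photosynthesize at a mass-dependent Michaelis-Menten rate,
    allocate energy in a fixed basal-metabolism : somatic-growth :
    reproduction ratio, compete for cell-level nutrients by contest, and
    reproduce semelparously at the end of each growing season, with
    tetraploid seeds arising recurrently from diploid parents. Includes
    experiment drivers for metabolic-efficiency sweeps, invasion and
    coexistence classification, carrying-capacity estimation, and mass and
    age structure summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
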