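Package: racewaysim
Title: Bioenergetic Growth and Dissolved-Oxygen Dynamics in Flow-Through
    Trout Raceways
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates rainbow-trout (Oncorhynchus mykiss) rearing cycles in
    land-based flow-through raceway basins.  An energy-budget growth model
    driven by water temperature, feed ration and feed composition is coupled
    to a one-dimensional streamwise model of dissolved oxygen (advection,
    atmospheric reaeration, a point oxygen source at the inlet, and a
    biomass-distributed respiration sink).  On top of the coupled model sit
    stocking-density management rules (utilization factor, fractional
    biomass transfers, intervention proposals) and oxygen-supply control
    policies, both open-loop schedules and closed-loop policies that match
    outlet to inlet concentration or enforce a welfare floor.  A synthetic
    forcing generator, a scenario engine with CSV export, and an oxygen
    mass-balance accountant support scenario analysis and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
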