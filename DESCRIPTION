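Package: hydrafor
Title: Tree Hydraulic Traits, Water Deficit and Forest Carbon Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drought sensitivity of tropical forests from
    field hydraulic measurements and permanent-plot censuses. Fits sigmoid
    xylem embolism vulnerability curves to pneumatic air-discharge data to
    estimate the water potentials at 50% and 88% embolism, computes hydraulic
    safety margins from dry-season leaf water potentials, derives
    climatological water-deficit metrics (maximum cumulative water deficit,
    dry-season length) from monthly rainfall and evapotranspiration, turns
    tree-by-tree census tables into plot-level biomass stocks and fluxes
    (net biomass change, woody production, biomass mortality, stem mortality
    rates, woody residence time), aggregates species traits to basal-area
    weighted community means, and links traits to forest dynamics with
    standardized major axis regressions. A seeded synthetic-data generator
    produces vulnerability curves, monthly climate series and birth-death-
    growth censuses with known ground truth so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
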