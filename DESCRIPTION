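Package: barleyclim
Title: Potential Yield Simulation and Climate Attribution for Highland Barley
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-timestep potential-production crop growth simulator for
    highland barley (WOFOST-style phenology, canopy assimilation, maintenance
    respiration and dry-matter partitioning), together with the surrounding
    agroclimatic analysis chain: preprocessing of raw station meteorology
    (Angstrom-Prescott radiation, Tetens vapour pressure, wind-profile
    height correction), thermal-time calibration and validation metrics,
    Mann-Kendall trend detection with Sen's slope, and first-difference
    climate-yield attribution by temperature zone using Pearson correlation
    and stepwise multiple linear regression. A seeded synthetic alpine
    weather generator makes the whole pipeline reproducible without access
    to station archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
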