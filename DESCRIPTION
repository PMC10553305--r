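Package: mpencounter
Title: Encounter Rates Between Zooplankton and Microplastics Under Calm
    and Wind-Driven Turbulent Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the rate at which individual zooplankters (copepods,
    chaetognaths, luciferid shrimps) encounter suspended microplastic
    particles in a shallow estuary. Implements the Gerritsen-Strickler
    ballistic encounter-rate model for calm water and the
    Rothschild-Osborn turbulence correction in which each swimming speed
    v is replaced by sqrt(v^2 + w^2), with w the wind-induced small-scale
    turbulent velocity. Includes a wind-forced vertical turbulence
    submodel (turbulent velocity, kinetic energy, dissipation rate with
    depth), a bootstrap engine over per-station particle concentrations
    producing mean and standard-deviation encounter-rate depth profiles,
    a brute-force Monte-Carlo oracle that validates the closed-form
    rates by simulating a searcher among Poisson-distributed particles
    in a periodic box, and a generator of synthetic station
    concentration sets matching published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
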