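Package: casevac
Title: Robust Hospital Location and Casualty Evacuation Planning for
    Earthquake Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves mixed-integer programs for post-earthquake
    casualty rescue over a three-tier chain: disaster areas feed temporary
    hospitals by road vehicle, and temporary hospitals feed general
    hospitals by helicopter.  The objective is the weighted Trauma Index
    Score accrued during transport, with severity-class deterioration
    rates that slow after field treatment.  Includes the deterministic
    location-allocation model, its budget-of-uncertainty robust
    counterpart for uncertain casualty counts, a two-stage dynamic
    extension with fleet-return recursions, and a generalized Benders
    decomposition solver, together with an embedded case study fixture
    (2013 Lushan earthquake), a seeded synthetic instance generator, and
    sensitivity and feasibility experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    boot
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
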