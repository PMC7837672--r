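Package: impulsim
Title: Mobile Impulsivity Task Battery Simulation and Psychometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Engines for three mobile behavioral impulsivity tasks (balloon
    risk task, cued go/no-go, adaptive delay discounting) with their standard
    scores, a 20-item semantic-differential instrument and photographic affect
    meter, a 21-day morning/evening ecological momentary assessment protocol,
    a synthetic-participant cohort simulator with correlated impulsivity
    traits, diurnal state shifts and mood-state coupling, and a psychometric
    validation pipeline (principal components with varimax rotation,
    reliability, convergent-validity and test-retest tables).  Task batteries
    are defined by a JSON step schema, sessions are logged as JSON Lines, and
    whole studies can be generated, simulated, scored and analyzed end to end
    with no real participants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
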