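Package: careops
Title: Optimization Toolkit for Ambulatory-Care Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support methods for ambulatory healthcare planning on
    street networks: turn-restriction-aware shortest paths and isochrone
    fields with robust-regression speed-profile estimation; exact
    vaccination-center location; exact and robust q-multiset-multicover
    provision of emergency doctors with an event-based dispatch simulator;
    annual out-of-hours pharmacy rostering with coverage, dispersion, rest,
    fairness and quarantine-robustness constraints; and lexicographic
    vehicle routing with soft time windows for patient transport, including
    online re-optimization and a nearest-available baseline. All methods run
    on seeded synthetic regions produced by the package's own generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
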