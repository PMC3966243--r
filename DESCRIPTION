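Package: pthpop
Title: Multi-Population Model of Parathyroid Hormone Secretion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates acute parathyroid hormone (PTH) responses to serum
    ionized-calcium clamp protocols with a population of heterogeneous
    parathyroid cell subpopulations. Each subpopulation secretes a
    calcium-inhibited fraction of its intracellular PTH store; secreted
    hormone distributes between serum and interstitial compartments and is
    cleared renally and hepatically. Includes idealized clamp protocols,
    closed-form steady states, distribution-based virtual-population
    sampling, iterative rejection-sampling calibration with kernel density
    re-estimation, steady-state slope and four-parameter sigmoid analyses,
    ensemble confidence bands, and a synthetic-observation generator for
    end-to-end testing of the calibration pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
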