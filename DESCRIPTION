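Package: daivequity
Title: Decision Analysis for Intervention Value Efficiency with Equitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing multicomponent behavioral interventions with
    health equity as an explicit criterion. Simulates 2^k factorial optimization
    randomized controlled trials (ORCTs) in which component effects depend on a
    continuous systemic-advantage measure, estimates posterior expected outcome
    gains per candidate intervention (overall and within advantage strata), and
    supports multi-criteria decision making: health-gain concentration curves and
    a concentration-based equitability index, net health value at configurable
    willingness-to-pay thresholds, the cost-outcome value efficiency frontier
    with incremental cost-effectiveness ratios, and the equitability versus
    net-health-value frontier whose members are the decision contenders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
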