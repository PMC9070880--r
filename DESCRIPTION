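Package: basinopt
Title: Hydroeconomic Optimization of River-Basin Water Allocation with
    Environmental Benefits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated hydroeconomic model for evaluating drought
    water-allocation policies in a river basin. Couples a reduced-form
    node-link hydrology (mass balance, flow continuity, minimum
    environmental flows) with irrigation-district economics calibrated by
    Positive Mathematical Programming, quadratic urban surplus, and an
    ecological component that maps stream flow to habitat (weighted usable
    area) and monetized environmental benefits. Solves welfare-maximizing
    allocations under institutional cooperation and water-market policy
    regimes, with and without environmental purchases, and reports the
    private/environmental/social benefit trade-offs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
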