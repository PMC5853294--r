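Package: tagflux
Title: Carbon-Flux Partitioning of Triacylglycerol Biosynthesis from
    Pulse-Chase Radiolabeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying carbon allocation into storage lipids
    from isotope pulse-chase experiments in microalgae under nitrogen
    deprivation. Converts scintillation counts to carbon amounts and pool
    masses via tracer specific activity, simulates first-order
    compartmental pool models under pulse/chase labeling protocols with
    replicate noise, partitions daily triacylglycerol (TAG) synthesis
    among starch degradation, direct de novo assimilation, and acyl
    transfer through newly made polar lipids, closes the resulting carbon
    budget against independently measured totals, and estimates pool-model
    rate constants and transfer fractions by weighted least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
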