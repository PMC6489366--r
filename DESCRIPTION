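Package: pskstab
Title: Plasmid Stability Dynamics with Post-Segregational Killing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulators and Bayesian inference for the segregational
    stability of bacterial plasmids protected by post-segregational killing
    (PSK) systems. Implements a two-population growth model of plasmid-bearing
    and plasmid-free cells covering toxin-antitoxin and secreted-bacteriocin
    killing, maps it onto serial dilute-and-regrow passaging and single-passage
    competition designs, and estimates the plasmid-loss probability, growth
    burden ratio and killing efficacy from observed loss curves with a
    hierarchical Bayesian ensemble sampler. Also provides an automated
    flow-cytometry gating pipeline (debris exclusion and log-fluorescence
    mixture modelling) to turn event-level data into plasmid-bearing
    fractions, a Gaussian-process estimator of maximal specific growth rate
    from optical-density curves, and seeded synthetic-data generators for
    all three data types with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
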