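Package: fuzztrack
Title: Observer-Based Robust H-Infinity Fuzzy Tracking Control of an Activated Sludge Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact Takagi-Sugeno (TS) fuzzy modelling of a four-state activated-sludge
    bioprocess by the sector-nonlinearity method, linear-matrix-inequality (LMI) synthesis
    of a reduced-order parallel-distributed-compensation (PDC) tracking controller with a
    guaranteed H-infinity disturbance-attenuation level, synthesis of a
    disturbance-augmented fuzzy Luenberger observer driven by the dissolved-oxygen
    measurement only, and a closed-loop simulator that verifies the certified performance
    under sinusoidal influent-substrate variation and temporary kinetic-parameter changes.
    Includes a small dense-block interior-point LMI feasibility solver implemented with
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
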