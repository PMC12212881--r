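Package: peonr
Title: Predictive-Coding Circuit Simulation and Omission-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-stream leaky integrate-and-fire predictive-coding
    microcircuits driven by oddball tone sequences with omissions, and
    implements the accompanying single-unit spike-train analysis pipeline:
    baseline-corrected omission responses, probability-encoding correlations,
    split-half classification of probability encoding omission neurons
    (PEONs), buildup and adaptation curve fits, selectivity indices, and
    laminar/areal bootstrap enrichment tests. A synthetic spike-train
    generator with planted ground truth makes every analysis stage testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
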