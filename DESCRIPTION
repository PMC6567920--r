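Package: pcdcea
Title: Cost-Effectiveness Analysis of Diagnostic Algorithms for Primary
    Ciliary Dyskinesia
Version: 0.1.0
Authors@R: person("pcdcea", "maintainers", email = "pcdcea@example.org",
    role = c("aut", "cre"))
Description: Probabilistic decision-analysis toolkit for comparing
    multi-test diagnostic algorithms for primary ciliary dyskinesia (PCD).
    Implements Bayes-theorem expected-value classification of a referral
    cohort under sequential and parallel test topologies (nasal nitric
    oxide, high-speed video microscopy, transmission electron microscopy),
    bottom-up micro-costing of each algorithm, Latin Hypercube
    probabilistic sensitivity analysis, and cost-effectiveness statistics:
    CER, ICER with dominance pruning, the cost-effectiveness frontier,
    acceptability curves and one-way (tornado) sensitivity analysis. A
    patient-level Bernoulli microsimulation doubles as synthetic-data
    generator and brute-force oracle for the analytic model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
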