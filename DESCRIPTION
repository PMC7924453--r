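Package: edflow
Title: Discrete-Event Simulation and Designed Experiments for Emergency
    Department Capacity Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates patient flow through an emergency department from
    triage to discharge or short-stay-unit transfer, with CTAS priority
    queueing, shift-scheduled staff pools, capacity-limited care areas,
    nonhomogeneous Poisson arrivals, probabilistic exam and specialist
    consult pathways, and seeded replication.  Provides KPI reporting with
    warm-up truncation and t-based confidence intervals, service-level and
    sensitivity analyses, one-sample equivalence testing, and an experiment
    layer: two-level full factorial and central composite designs, effect
    estimation with Lenth pseudo-standard-error screening, quadratic
    response-surface fits with adjusted and predicted R-squared, and
    lexicographic capacity recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
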