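Package: triagesim
Title: Discrete-Event Simulation of AI-Prioritized Radiology Worklists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulation of chest X-ray worklist processing in a
    radiology department. Models time-of-day-conditioned exam arrival and
    reporting processes, prevalence-based multi-label ground truth, an
    imperfect multi-label classifier described by per-finding operating
    points or a binormal ROC surrogate, and worklist policies (first-in
    first-out, urgency prioritization, maximum-waiting-time promotion, and
    a perfect-classifier upper bound). Computes per-finding report
    turnaround time statistics, Welch t-test strategy comparisons and
    operating-point sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
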