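Package: swhunt
Title: Efficient Incomplete Stepped Wedge Designs with Continuous Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing stepped wedge cluster randomised trials in
    which participants present continuously and recruitment may be suspended
    at chosen cluster/time slots ("incomplete" designs). Computes the exact
    generalised least squares variance of the treatment effect estimator
    under a polynomial secular trend and an exponentially decaying
    intracluster correlation, and hunts for efficient designs at a target
    power with an iterative greedy search over time-and-condition-reversal
    symmetric schedules, with staircase and random symmetric designs as
    baselines. Includes a bit-exact CSV schedule format and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
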