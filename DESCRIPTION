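Package: nicheshift
Title: Ecological Niche Modeling, Climate-Scenario Projection, and
    Niche-Overlap Vulnerability Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for presence-background ecological
    niche modeling of interacting species pairs: occurrence cleaning and
    grid thinning, target-group sampling-bias surfaces and weighted
    pseudo-absence sampling, a native maximum-entropy (Gibbs log-linear)
    suitability estimator with L1 regularization and AICc-based selection
    of the regularization multiplier, projection onto past and future
    climate-scenario layer stacks with GCM ensemble averaging, Schoener's
    D and Warren's I niche-overlap metrics, and a threshold-free
    percent-change vulnerability assessment over species ranges and their
    geographic intersection. Includes a synthetic-data generator with
    known ground truth so every stage of the analysis is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
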