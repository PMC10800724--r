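Package: insightrl
Title: Q-Learning Trait Estimation from Bandit Behavior and Probit
    Analysis of Insight Problem Solving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-armed bandit (TAB) sessions under a
    reversal reward schedule, fits a prospect-utility Q-learning model
    with asymmetric learning rates and a perseveration term to
    trial-level choice data by per-subject maximum a posteriori
    estimation, and analyzes the effect of the seven estimated learning
    traits on binary insight-task outcomes (8-coin and 9-dot problems)
    through probit regressions, order-split subsample analyses and
    success-rate comparisons. A synthetic cohort generator emulates the
    full study design (enrollment, exclusions, task order, cross-task
    learning transfer) so that every stage of the pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
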