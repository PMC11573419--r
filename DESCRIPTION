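Package: sepsisrl
Title: Offline Reinforcement Learning for Sepsis Treatment Policies from ICU Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds discrete Markov decision processes from 4-hour-binned
    intensive-care time series of septic patients, solves them by policy
    iteration, and evaluates vasopressor and intravenous-fluid dosing policies
    against the clinician behaviour policy with bootstrapped weighted
    importance sampling. Includes a synthetic septic-cohort generator with a
    latent severity process, cohort-definition and preprocessing rules
    (sepsis-onset identification, exclusions, 4-hour binning, value capping,
    zero-order-hold imputation), k-means++ state discretization with
    feature-subset and principal-component state representations, a 25-level
    treatment action grid, rare-transition filtering, temporal-difference
    evaluation of the behaviour policy, and an experiment driver for
    repeated-clustering model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
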