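Package: migrar
Title: Bayesian Hierarchical AR(1) Projection of Net International Migration
Version: 0.1.0
Authors@R:
    person("Migration Modelling", "Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic projection of net international migration rates and
    counts for all countries. Fits a three-level Bayesian hierarchical
    first-order autoregressive model to per-country net migration rates by
    Markov chain Monte Carlo (conjugate Gibbs updates with slice sampling for
    the non-conjugate hyperparameters), simulates joint posterior-predictive
    trajectories with an age- and sex-specific zero-global-net-migration
    correction, and evaluates forecasts out of sample against persistence and
    gravity-model baselines. Includes a synthetic-data generator with known
    ground truth, global migration-trend statistics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
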