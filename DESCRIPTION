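Package: seqchoice
Title: Models of Preferences for Sequences of Delayed Monetary Gains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling binary choices between sequences of delayed
    monetary gains presented on a shared period grid. Implements four
    candidate choice models -- a tradeoff model in which accumulated outcome
    utility is weighed against the duration of utility accumulation
    (a cumulative weighing of time), a discounted instantaneous utility
    model, and two variants of the improvement/spreading sequences model
    differing in their treatment of concealed zero outcomes -- together with
    a random-choice baseline. Provides stimulus construction and screening
    on net-present-value and duration criteria, individual-level Bayesian
    model comparison via Monte-Carlo marginal likelihoods and Bayes factors,
    group-level posterior estimation by adaptive Metropolis-Hastings with
    highest-density-interval summaries, posterior-predictive model checking,
    model- and parameter-recovery simulations, and synthetic-cohort
    generators including hidden-zero framing designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
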