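Package: painhmm
Title: Bayesian Hidden Markov Modelling of Pain Perception and Chronification
Version: 0.1.0
Authors@R: person("painhmm", "maintainers", email = "maintainers@painhmm.org",
    role = c("aut", "cre"))
Description: A generative Bayesian observer model of pain perception. Hidden
    pain states form a two-state Markov chain observed through noxious or
    harmless sensations; beliefs over priors, transitions and likelihoods are
    categorical distributions with Dirichlet pseudocounts. The package provides
    exact sum-product inference on the chain (with unobserved nodes), batch
    free-energy learning across trials, preset healthy and chronic-pain
    observers, a null-space construction of transition tables stationary for a
    target pain marginal (a mechanism for treatment-resistant chronic pain),
    and named simulation scenarios with a command-line interface.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
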