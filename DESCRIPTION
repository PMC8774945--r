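Package: qsdlearn
Title: Learning Quasi-Stationary Distributions of Absorbing Markov Chains
Version: 0.1.0
Authors@R: person("QSD", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for computing and learning the quasi-stationary
    distribution (QSD) of a strictly sub-Markovian transition kernel on a
    finite state space. Provides exact eigenvector and linear-algebra
    reference solvers, an average-reward actor-critic algorithm that learns
    the QSD as the softmax policy maximising the (negative) Kullback-Leibler
    divergence rate between the path measures of two regenerative kernels,
    the classical single-particle empirical scheme, projected stochastic
    approximation with Polyak averaging, and a Fleming-Viot particle system.
    Includes generators for benchmark chains (loopy chain, absorbed M/M/1/N
    queue, SIS-type epidemic extinction chain, random sub-Markovian
    instances) and a small command line interface for reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
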