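Package: sourceflow
Title: Contagion Source Detection via Snapshot Likelihoods and Multicast Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying the source of a contagion ("infodemic")
    on a network from a single snapshot of infected nodes. Implements exact
    snapshot likelihoods for a generalized Susceptible-Infectious model via
    phase-type (hypoexponential) convolutions, the classical first-k and
    joint maximum-likelihood source estimators together with a
    random-observation-time estimator that resolves their degeneracy, and a
    rate-constrained formulation of source detection on information-flow
    networks: polylinking functions, four multicast capacities (multi-source,
    single-source, multiple-access, unicast) for directed and undirected
    graphs, backward-elimination search for inclusion-minimal feasible
    sources, and greedy and lazy-greedy forward selection under a source
    budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
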