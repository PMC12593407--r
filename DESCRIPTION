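Package: atlrxn
Title: Active Transfer Learning for Reaction-Condition Exploration
Version: 0.1.0
Authors@R:
    person("atlrxn", "maintainers", email = "atlrxn@example.org", role = c("aut", "cre"))
Description: Batch selection of reaction conditions over a combinatorial
    reagent space (precatalyst x ligand x additive x solvent) by active
    transfer learning: an ensemble of depth-limited random-forest
    classifiers trained on a related source reaction domain votes on
    candidate conditions, failed suggestions prune the trees that endorsed
    them, and each batch of new target-domain results trains a fresh
    generation of models that is merged into the ensemble. Includes reagent
    catalog I/O and featurization (physical descriptors plus one-hot
    precatalysts and additive ions), a synthetic yield-landscape simulator
    with shared-ligand source/target structure for end-to-end testing
    without laboratory data, baseline strategies and a benchmark harness,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
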