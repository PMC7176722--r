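Package: chemoDTI
Title: Chemogenomic Drug-Target Interaction Prediction and Benchmarking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Similarity-based prediction of binary drug-target interactions
    (DTIs) from a bipartite interaction matrix together with drug-drug and
    target-target similarity kernels. Implements the classical chemogenomic
    method family: nearest-profile and weighted-profile baselines, weighted
    nearest-neighbour profile inference feeding Kronecker regularized
    least-squares with Gaussian interaction profile (GIP) kernels,
    network-based inference by two-step mass diffusion on the bipartite
    graph, and collaborative matrix factorization variants (CMF, multiple
    similarity CMF, and weighted graph regularized matrix factorization).
    Ships the three standard cross-validation regimes (held-out pairs,
    held-out drugs, held-out targets), per-fold AUC/AUPR evaluation with
    mean and standard deviation aggregation, a synthetic bipartite data
    generator for self-contained benchmarking, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'data-model.R'
    'io.R'
    'profiles.R'
    'nbi.R'
    'kron-rls.R'
    'factorization.R'
    'evaluation.R'
    'methods-registry.R'
    'synthetic.R'
    'cli.R'
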