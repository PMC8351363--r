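Package: dhrls
Title: Dual Hypergraph Regularized Least Squares for Bipartite Link Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts missing links in bipartite biological networks
    (e.g. gene-disease associations) by dual hypergraph regularized least
    squares (DHRLS) with centered kernel alignment based multiple kernel
    learning (CKA-MKL). Includes Gaussian interaction profile kernels,
    DAG-based disease semantic similarity, cosine and normalized
    Smith-Waterman similarity kernels, kNN hypergraph Laplacians, an
    alternating least squares solver with graph-regularized (DGRLS) and
    LapRLS baselines, pair-holdout and cold-start cross-validation with
    AUC/AUPR, and a synthetic block-structured network generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
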