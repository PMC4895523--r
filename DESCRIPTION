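Package: sparseAE
Title: Sparse Autoencoders for Hierarchical Representation of
    Perturbation Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns hierarchical representations of binarized
    perturbation expression compendia with stacked restricted Boltzmann
    machines (sparse deep autoencoders). Provides binarization and
    prevalence filtering of log-ratio matrices, contrastive-divergence
    training with a hidden-activation sparsity penalty, greedy
    layer-wise pretraining with backpropagation fine-tuning,
    architecture selection by cross-validated reconstruction error and
    a Bernoulli-likelihood Bayesian information criterion,
    interpretation of hidden units as transcription factors and
    pathways via weight thresholding and hypergeometric enrichment, a
    non-negative matrix factorization baseline, consensus clustering of
    samples under alternative representations, and a synthetic
    hierarchical regulatory-network generator with planted ground truth
    for recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cluster,
    mclust,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
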