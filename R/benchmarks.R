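#' Planted-network recovery and representation benchmarks
#'
#' Standardized end-to-end experiments on synthetic compendia with planted
#' ground truth, used to characterize what the trained models recover.
#' All three run the full pipeline: simulate -> binarize at 3-fold ->
#' prevalence filter -> train -> interpret.
#'
#' `benchmarkTFRecovery` scores the Fig-3-style question: after training a
#' sparse autoencoder whose first hidden layer has as many units as there
#' are planted TFs, what fraction of TFs is recovered as the significant
#' best hit of exactly one unit (top-15% weight gene sets, hypergeometric
#' mapping, BH 0.05)? The NMF baseline with the same rank is scored
#' identically on the same data.
#'
#' @param seed integer seed for this replicate (network, data and training).
#' @param nSamples number of simulated arrays (default 500).
#' @param config a [networkConfig()]; the default study conditions plant
#'   200 genes, 20 TFs and 5 pathways.
#' @param hyper training settings; the default is the package's reference
#'   recipe for these problem sizes.
#' @param nUnits first-hidden-layer size (defaults to the number of TFs).
#' @param fraction weight-threshold fraction (default 0.15).
#' @param alpha BH significance level (default 0.05).
#' @return `benchmarkTFRecovery`: named numeric vector with elements
#'   `autoencoder` and `nmf` (one-to-one recovery fractions).
#' @export
benchmarkTFRecovery <- function(seed, nSamples = 500,
                                config = networkConfig(seed = seed),
                                hyper = trainParams(learningRate = 0.1,
                                                    nEpochs = 400,
                                                    batchSize = 50,
                                                    weightDecay = 1e-3,
                                                    sparsityTarget = 0.15,
                                                    sparsityLambda = 0.3,
                                                    seed = seed),
                                nUnits = config@nTFs, fraction = 0.15,
                                alpha = 0.05) {
  net <- generateNetwork(config)
  se <- simulateCompendium(net, config, nSamples)
  X <- .as_gene_matrix(filterGenes(binarizeExpression(se)), "binary")
  model <- pretrainAutoencoder(X, nUnits, hyper)
  gsAE <- thresholdTopFraction(effectiveWeights(model, 1L), fraction)
  recAE <- oneToOneRecovery(mapUnitsToTFs(gsAE, tfTargets(net), alpha))
  nf <- nmfFactorize(X, nUnits)
  gsNMF <- thresholdTopFraction(nf$W, fraction)
  recNMF <- oneToOneRecovery(mapUnitsToTFs(gsNMF, tfTargets(net), alpha))
  c(autoencoder = as.numeric(recAE), nmf = as.numeric(recNMF))
}

#' @describeIn benchmarkTFRecovery Contrast of mean hidden activation
#'   between a sparse (target p, lambda > 0) and a dense (lambda = 0) model
#'   trained on the same data and architecture — the histogram contrast of
#'   expected hidden states.
#' @param sparsityTarget sparsity target p of the sparse model.
#' @param sparsityLambda penalty weight of the sparse model.
#' @return `benchmarkSparsityContrast`: named vector `sparse`/`dense` of
#'   mean hidden activation probabilities on the training data.
#' @export
benchmarkSparsityContrast <- function(seed, nSamples = 500,
                                      config = networkConfig(seed = seed),
                                      sparsityTarget = 0.1,
                                      sparsityLambda = 10,
                                      nUnits = config@nTFs) {
  net <- generateNetwork(config)
  se <- simulateCompendium(net, config, nSamples)
  X <- .as_gene_matrix(filterGenes(binarizeExpression(se)), "binary")
  base <- trainParams(learningRate = 0.1, nEpochs = 150, batchSize = 50,
                      weightDecay = 1e-3, sparsityTarget = sparsityTarget,
                      sparsityLambda = sparsityLambda, seed = seed)
  dense <- base; dense$sparsityLambda <- 0
  mS <- trainRBM(X, nUnits, base)
  mD <- trainRBM(X, nUnits, dense)
  c(sparse = mean(hiddenConditional(mS, X)),
    dense = mean(hiddenConditional(mD, X)))
}

#' @describeIn benchmarkTFRecovery Consensus-clustering recovery of planted
#'   sample groups under alternative representations. Samples are simulated
#'   with single-pathway perturbations so the planted grouping is the
#'   perturbed pathway; clustering with k = number of pathways is scored by
#'   adjusted Rand index against it for the raw binary genes, the NMF
#'   coefficients and the hidden-layer representation.
#' @param k number of clusters (defaults to the number of pathways).
#' @param nResamples consensus resampling rounds (default 50).
#' @return `benchmarkClustering`: named vector of ARIs (`hidden`, `nmf`,
#'   `genes`) plus separation scores as attribute `"separation"`.
#' @export
benchmarkClustering <- function(seed, nSamples = 300,
                                config = networkConfig(
                                  seed = seed,
                                  pathwaysPerExperiment = c(1, 1)),
                                k = config@nPathways, nResamples = 50,
                                nUnits = config@nTFs) {
  net <- generateNetwork(config)
  se <- simulateCompendium(net, config, nSamples)
  X <- .as_gene_matrix(filterGenes(binarizeExpression(se)), "binary")
  truth <- vapply(perturbedPathways(se), paste, character(1), collapse = ",")
  hyper <- trainParams(learningRate = 0.1, nEpochs = 300, batchSize = 50,
                       weightDecay = 1e-3, sparsityTarget = 0.15,
                       sparsityLambda = 0.3, seed = seed)
  model <- pretrainAutoencoder(X, nUnits, hyper)
  cmp <- compareRepresentations(X, model, nmfRank = nUnits, k = k,
                                truth = truth, nResamples = nResamples,
                                seed = seed)
  out <- c(hidden = unname(cmp$ari["hidden"]), nmf = unname(cmp$ari["nmf"]),
           genes = unname(cmp$ari["genes"]))
  attr(out, "separation") <- stats::setNames(cmp$scores$separation,
                                             cmp$scores$representation)
  out
}
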