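#' Deterministic k-fold split
#'
#' Partitions `n` samples into `k` folds whose sizes differ by at most one,
#' by shuffling under `seed` and dealing fold labels round-robin.
#'
#' @param n number of samples (>= k).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return Integer vector of fold labels in `1..k`, one per sample.
#' @export
kfoldSplit <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("'n' must be at least 'k'")
  withSeed(seed, {
    folds <- integer(n)
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Architecture and sparsity grid for model selection
#'
#' The default grid is the reference search: first hidden layer from 100 to
#' 428 in steps of 50 with the two anchor sizes 214 and 428 included
#' (7 values), second layer in \{50, 100\}, third and fourth layers fixed at
#' 50 and 25 — 14 architectures per model type — and sparsity constants
#' 0.05, 0.1, 0.15 for the sparse model alongside the dense one.
#'
#' @param h1 candidate sizes of hidden layer 1.
#' @param h2 candidate sizes of hidden layer 2 (`NULL` for single-layer
#'   grids).
#' @param h3,h4 fixed sizes of layers 3 and 4 (`NULL` to omit the layer).
#' @param sparsity sparsity targets for sparse models.
#' @param includeDense also evaluate the unpenalized model.
#' @return A list of class `"selectionGrid"` with an `architectures` list.
#' @export
selectionGrid <- function(h1 = c(100, 150, 200, 214, 250, 300, 428),
                          h2 = c(50, 100), h3 = 50, h4 = 25,
                          sparsity = c(0.05, 0.1, 0.15),
                          includeDense = TRUE) {
  if (length(h1) < 1L || any(h1 < 1)) stop("'h1' must be positive sizes")
  if (!is.null(h2) && any(h2 < 1)) stop("'h2' must be positive sizes")
  archs <- list()
  for (a in h1) {
    if (is.null(h2)) {
      archs[[length(archs) + 1L]] <- c(a, h3, h4)
    } else {
      for (b in h2) archs[[length(archs) + 1L]] <- c(a, b, h3, h4)
    }
  }
  archs <- lapply(archs, as.integer)  # c() already drops NULL h3/h4
  structure(list(h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                 architectures = archs, sparsity = sparsity,
                 includeDense = includeDense),
            class = "selectionGrid")
}

#' Number of architectures enumerated by a grid
#'
#' `|h1| * |h2|` per model type (the reference grid gives `7 * 2 = 14`).
#'
#' @param grid a [selectionGrid()].
#' @return Integer count.
#' @export
countGrid <- function(grid) {
  stopifnot(inherits(grid, "selectionGrid"))
  length(grid$architectures)
}

#' Free-parameter count of a stacked architecture
#'
#' Dense: `sum_k (D_k * F_k + D_k + F_k)` over the stacked RBMs. Sparse
#' models use the effective-parameter convention
#' `k = p * (dense weight count) + all biases`: with target p only that
#' fraction of the weights is effectively engaged, which reproduces the
#' structure of reported sparse BIC penalty terms being p times the dense
#' ones.
#'
#' @param arch integer vector of hidden-layer sizes.
#' @param nGenes visible-layer size.
#' @param sparsity `NULL` (dense) or the sparsity target p.
#' @return Parameter count (numeric).
#' @examples
#' countParameters(2, nGenes = 4)  # 4*2 + 4 + 2 = 14
#' @export
countParameters <- function(arch, nGenes, sparsity = NULL) {
  sizes <- c(nGenes, as.numeric(arch))
  wts <- sum(sizes[-length(sizes)] * sizes[-1L])
  biases <- sum(sizes[-length(sizes)]) + sum(sizes[-1L])
  if (is.null(sparsity)) wts + biases else sparsity * wts + biases
}

#' Bayesian information criterion for binary reconstruction
#'
#' `BIC = -2 ln L + k ln(n)` with the Bernoulli likelihood
#' `L = prod_cells p^m (1-p)^(1-m)` taken over all gene x sample cells,
#' where p is the model's reconstruction probability and m the observed
#' binary state. Probabilities are clipped to `[1e-12, 1 - 1e-12]` so the
#' log-likelihood is finite. Lower is better.
#'
#' @param reconProbs matrix of predicted probabilities.
#' @param data binary matrix of the same shape (or `SummarizedExperiment`).
#' @param k free-parameter count (see [countParameters()]).
#' @param nSamples sample count n used in the `k ln(n)` penalty.
#' @return The BIC value, with the two components attached as
#'   `attr(, "components")` (`minus2LogLik`, `penalty`).
#' @examples
#' bicScore(matrix(0.5, 2, 2), matrix(c(1, 0, 0, 1), 2, 2), k = 2,
#'          nSamples = 1)  # 8 log(2)
#' @export
bicScore <- function(reconProbs, data, k, nSamples) {
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  if (!identical(dim(X), dim(reconProbs)))
    stop("'reconProbs' and 'data' must have identical dimensions")
  if (k <= 0 || nSamples <= 0) stop("'k' and 'nSamples' must be positive")
  eps <- 1e-12
  p <- pmin(pmax(reconProbs, eps), 1 - eps)
  ll <- sum(X * log(p) + (1 - X) * log(1 - p))
  out <- -2 * ll + k * log(nSamples)
  attr(out, "components") <- c(minus2LogLik = -2 * ll,
                               penalty = k * log(nSamples))
  out
}

#' Cross-validated architecture and sparsity selection
#'
#' For every architecture in the grid and every model type (dense and each
#' sparsity target), trains on each of `folds` training splits, records the
#' mean training and held-out reconstruction error, then refits on the full
#' data to compute the BIC (BIC is a whole-data criterion; cross-validation
#' supplies the error estimates). The preferred model is the one with the
#' lowest BIC.
#'
#' @param data binary gene x sample matrix or `SummarizedExperiment`.
#' @param grid a [selectionGrid()].
#' @param hyper a [trainParams()] list (its `sparsityTarget`/`sparsityLambda`
#'   are overridden per model type; `sparsityLambda` must be > 0 for sparse
#'   cells, default 1 if unset).
#' @param folds number of cross-validation folds (default 10).
#' @param seed seed controlling the fold split and training streams.
#' @param finetune also run backpropagation fine-tuning on each fit.
#' @return A list of class `"selectionReport"`: `report` (data.frame with
#'   one row per grid cell x model type: architecture, sparsity, parameter
#'   count k, mean train/test error, BIC and its two components) and `best`
#'   (the row index with minimum BIC).
#' @export
selectModel <- function(data, grid, hyper = trainParams(), folds = 10L,
                        seed = 1L, finetune = FALSE) {
  stopifnot(inherits(grid, "selectionGrid"))
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  n <- ncol(X)
  fold <- kfoldSplit(n, folds, seed)
  types <- list()
  if (grid$includeDense) types <- c(types, list(list(name = "dense", p = NA)))
  for (p in grid$sparsity)
    types <- c(types, list(list(name = "sparse", p = p)))
  rows <- list()
  for (ai in seq_along(grid$architectures)) {
    arch <- grid$architectures[[ai]]
    for (ty in types) {
      hy <- hyper
      if (ty$name == "dense") {
        hy$sparsityLambda <- 0
      } else {
        hy$sparsityTarget <- ty$p
        if (hy$sparsityLambda <= 0) hy$sparsityLambda <- 1
      }
      trainErr <- testErr <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- X[, fold != f, drop = FALSE]
        te <- X[, fold == f, drop = FALSE]
        hy$seed <- seed + 1000L * f + ai
        fit <- pretrainAutoencoder(tr, arch, hy)
        if (finetune) fit <- finetuneAutoencoder(fit, tr, hy)
        trainErr[f] <- reconstructionError(tr, reconstruct(fit, tr))
        testErr[f] <- reconstructionError(te, reconstruct(fit, te))
      }
      hy$seed <- seed + ai
      full <- pretrainAutoencoder(X, arch, hy)
      if (finetune) full <- finetuneAutoencoder(full, X, hy)
      k <- countParameters(arch, nrow(X),
                           if (ty$name == "dense") NULL else ty$p)
      bic <- bicScore(reconstruct(full, X), X, k, n)
      rows[[length(rows) + 1L]] <- data.frame(
        architecture = paste(arch, collapse = "-"),
        type = ty$name, sparsity = ty$p, k = k,
        trainError = mean(trainErr), testError = mean(testErr),
        bic = as.numeric(bic),
        minus2LogLik = attr(bic, "components")[["minus2LogLik"]],
        penalty = attr(bic, "components")[["penalty"]],
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  structure(list(report = report, best = which.min(report$bic),
                 folds = folds, seed = seed),
            class = "selectionReport")
}
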