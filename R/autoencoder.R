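#' Greedy layer-wise pretraining of a stacked autoencoder
#'
#' Trains a stack of (sparse) RBMs bottom-up: layer 1 on the binary data,
#' each subsequent layer on the expected hidden activations (mean-field
#' probabilities, no sampling) of the layer below. Deterministic given
#' `hyper$seed` (each layer trains with a distinct seed derived from it).
#'
#' @param data gene x sample binary matrix or `SummarizedExperiment` with a
#'   `"binary"` assay.
#' @param arch integer vector of hidden layer sizes, bottom first (the
#'   reference full-scale configuration is `c(214, 100, 50, 25)`).
#' @param hyper a [trainParams()] list applied to every layer.
#' @return A [DeepAutoencoder] with per-layer reconstruction-error traces in
#'   the `training` slot.
#' @examples
#' x <- matrix(rbinom(4 * 40, 1, 0.3), 4, 40)
#' m <- pretrainAutoencoder(x, arch = 2,
#'                          hyper = trainParams(nEpochs = 3, batchSize = 10))
#' m
#' @export
pretrainAutoencoder <- function(data, arch, hyper = trainParams()) {
  m <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  .check_unit_interval(m, "data")
  arch <- as.integer(arch)
  if (length(arch) < 1L || any(arch < 1L)) stop("invalid architecture")
  rbms <- vector("list", length(arch))
  traces <- vector("list", length(arch))
  input <- m
  for (k in seq_along(arch)) {
    hk <- hyper
    hk$seed <- hyper$seed + (k - 1L)  # distinct stream per layer
    rbms[[k]] <- trainRBM(input, arch[k], hk)
    traces[[k]] <- attr(rbms[[k]], "errorTrace")
    attr(rbms[[k]], "errorTrace") <- NULL
    input <- hiddenConditional(rbms[[k]], input)
  }
  new("DeepAutoencoder", rbms = rbms, architecture = as.numeric(arch),
      finetuned = FALSE,
      training = list(hyper = hyper, seed = hyper$seed,
                      pretrainTraces = traces))
}

## Forward pass of the unrolled encoder/decoder with tied weights.
## Returns encoder activations hs (list, hs[[1]] = input) and decoder
## activations ds (ds[[L+1]] = code, ds[[1]] = reconstruction).
.ae_forward <- function(rbms, X) {
  L <- length(rbms)
  hs <- vector("list", L + 1L)
  hs[[1L]] <- X
  for (k in seq_len(L))
    hs[[k + 1L]] <- sigmoid(crossprod(rbms[[k]]@W, hs[[k]]) + rbms[[k]]@b)
  ds <- vector("list", L + 1L)
  ds[[L + 1L]] <- hs[[L + 1L]]
  for (k in rev(seq_len(L)))
    ds[[k]] <- sigmoid(rbms[[k]]@W %*% ds[[k + 1L]] + rbms[[k]]@a)
  list(hs = hs, ds = ds)
}

#' Loss and analytic gradient of the unrolled autoencoder
#'
#' Computes the mean-per-sample cross-entropy between `data` and its
#' reconstruction through the unrolled encoder/decoder (weights tied between
#' the two passes, so the parameter set is exactly the stacked RBMs'
#' `{W, a, b}`), together with its analytic gradient by backpropagation.
#' Exposed so the gradient can be checked against finite differences.
#'
#' When `sparsityLambda > 0` the minimized objective adds the same
#' activation-sparsity term as RBM training,
#' `lambda * sum_layers sum_j (p - qbar_j)^2` with `qbar_j` the batch-mean
#' encoder activation of unit j, so fine-tuning preserves the sparse regime.
#'
#' @param model a [DeepAutoencoder].
#' @param data D x n matrix in \[0, 1\].
#' @param sparsityTarget target mean activation p.
#' @param sparsityLambda penalty weight lambda (0 disables).
#' @return List with `loss` (scalar, penalty included) and `grads` (per
#'   layer: `W`, `a`, `b`).
#' @export
autoencoderGradient <- function(model, data, sparsityTarget = 0.1,
                                sparsityLambda = 0) {
  stopifnot(is(model, "DeepAutoencoder"))
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  rbms <- model@rbms
  L <- length(rbms)
  B <- ncol(X)
  fw <- .ae_forward(rbms, X)
  hs <- fw$hs; ds <- fw$ds
  eps <- 1e-12
  yhat <- pmin(pmax(ds[[1L]], eps), 1 - eps)
  loss <- -sum(X * log(yhat) + (1 - X) * log(1 - yhat)) / B
  if (sparsityLambda > 0)
    for (k in seq_len(L))
      loss <- loss + sparsityLambda *
        sum((sparsityTarget - rowMeans(hs[[k + 1L]]))^2)
  grads <- lapply(rbms, function(r)
    list(W = matrix(0, nrow(r@W), ncol(r@W)),
         a = numeric(length(r@a)), b = numeric(length(r@b))))
  ## decoder sweep: delta is the preactivation gradient at decoder level k-1
  delta <- (ds[[1L]] - X) / B           # cross-entropy + sigmoid shortcut
  for (k in seq_len(L)) {
    grads[[k]]$W <- grads[[k]]$W + delta %*% t(ds[[k + 1L]])
    grads[[k]]$a <- grads[[k]]$a + rowSums(delta)
    e <- crossprod(rbms[[k]]@W, delta)  # value gradient at ds[[k+1]]
    if (k < L) {
      delta <- e * ds[[k + 1L]] * (1 - ds[[k + 1L]])
    } else {
      delta <- e * hs[[L + 1L]] * (1 - hs[[L + 1L]])  # enters the encoder top
    }
  }
  ## encoder sweep; the sparsity penalty feeds in as a value gradient on
  ## each encoder layer's activations
  spen <- function(k) {
    if (sparsityLambda == 0) return(0)
    h <- hs[[k + 1L]]
    -2 * sparsityLambda * (sparsityTarget - rowMeans(h)) / B
  }
  delta <- delta + spen(L) * hs[[L + 1L]] * (1 - hs[[L + 1L]])
  for (k in rev(seq_len(L))) {
    grads[[k]]$W <- grads[[k]]$W + hs[[k]] %*% t(delta)
    grads[[k]]$b <- grads[[k]]$b + rowSums(delta)
    if (k > 1L) {
      e <- rbms[[k]]@W %*% delta + spen(k - 1L)
      delta <- e * hs[[k]] * (1 - hs[[k]])
    }
  }
  list(loss = loss, grads = grads)
}

#' Fine-tune a pretrained autoencoder by backpropagation
#'
#' Unrolls the stack into an encoder/decoder with tied weights and minimizes
#' the reconstruction cross-entropy by mini-batch stochastic gradient
#' descent with momentum; when `hyper$sparsityLambda > 0` the objective
#' keeps the activation-sparsity term, so a sparse autoencoder stays sparse
#' through fine-tuning. Deterministic given `hyper$seed`. Zero epochs
#' returns the model unchanged; a non-finite loss aborts with the epoch
#' index.
#'
#' @param model a [DeepAutoencoder] from [pretrainAutoencoder()].
#' @param data the training matrix (or `SummarizedExperiment`).
#' @param hyper a [trainParams()] list (`learningRate`, `momentum` schedule,
#'   `nEpochs`, `batchSize`, `seed` are used).
#' @return The fine-tuned [DeepAutoencoder]; the per-epoch cross-entropy
#'   trace is stored in `training$finetuneTrace`.
#' @export
finetuneAutoencoder <- function(model, data, hyper = trainParams()) {
  stopifnot(is(model, "DeepAutoencoder"))
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  if (nrow(X) != nrow(model@rbms[[1L]]@W))
    stop("data row count does not match the model's visible layer")
  if (hyper$nEpochs == 0L) return(model)
  rbms <- model@rbms
  L <- length(rbms)
  n <- ncol(X)
  withSeed(hyper$seed, {
    vel <- lapply(rbms, function(r)
      list(W = matrix(0, nrow(r@W), ncol(r@W)),
           a = numeric(length(r@a)), b = numeric(length(r@b))))
    trace <- numeric(hyper$nEpochs)
    tmp <- new("DeepAutoencoder", rbms = rbms,
               architecture = model@architecture, finetuned = FALSE,
               training = list())
    for (ep in seq_len(hyper$nEpochs)) {
      mom <- if (ep > hyper$momentumSwitch) hyper$momentumFinal
             else hyper$momentum
      ord <- sample.int(n)
      starts <- seq(1L, n, by = hyper$batchSize)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + hyper$batchSize - 1L, n)]
        tmp@rbms <- rbms
        g <- autoencoderGradient(tmp, X[, idx, drop = FALSE],
                                 sparsityTarget = hyper$sparsityTarget,
                                 sparsityLambda = hyper$sparsityLambda)
        if (!is.finite(g$loss))
          stop(sprintf("fine-tuning diverged (non-finite loss) at epoch %d", ep))
        for (k in seq_len(L)) {
          vel[[k]]$W <- mom * vel[[k]]$W - hyper$learningRate * g$grads[[k]]$W
          vel[[k]]$a <- mom * vel[[k]]$a - hyper$learningRate * g$grads[[k]]$a
          vel[[k]]$b <- mom * vel[[k]]$b - hyper$learningRate * g$grads[[k]]$b
          rbms[[k]]@W <- rbms[[k]]@W + vel[[k]]$W
          rbms[[k]]@a <- rbms[[k]]@a + vel[[k]]$a
          rbms[[k]]@b <- rbms[[k]]@b + vel[[k]]$b
        }
        losses[bi] <- g$loss
      }
      trace[ep] <- mean(losses)
    }
    training <- model@training
    training$finetuneTrace <- trace
    training$finetuneHyper <- hyper
    new("DeepAutoencoder", rbms = rbms, architecture = model@architecture,
        finetuned = TRUE, training = training)
  })
}

#' Expected hidden activations at a given layer
#'
#' Deterministic mean-field upward pass: the conditional activation
#' probabilities of each layer are fed as expected values into the next
#' (no sampling), giving for every sample the probability of each hidden
#' unit to be on.
#'
#' @param model a [DeepAutoencoder].
#' @param data D x n matrix in \[0, 1\] or `SummarizedExperiment`.
#' @param layer hidden layer index in `1..nLayers(model)`.
#' @return unit x sample matrix of activation probabilities in \[0, 1\],
#'   with unit ids `L<layer>U<unit>`.
#' @export
inferHidden <- function(model, data, layer = 1L) {
  stopifnot(is(model, "DeepAutoencoder"))
  if (layer < 1L || layer > length(model@rbms))
    stop(sprintf("'layer' must be in 1..%d", length(model@rbms)))
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  cur <- X
  for (k in seq_len(layer)) cur <- hiddenConditional(model@rbms[[k]], cur)
  rownames(cur) <- sprintf("L%dU%02d", layer, seq_len(nrow(cur)))
  colnames(cur) <- colnames(X)
  cur
}

#' Probabilistic reconstruction of the input
#'
#' Mean-field encode to the top layer, then decode back down with the
#' visible conditionals; a columnwise (per-sample) map.
#'
#' @inheritParams inferHidden
#' @return Matrix of reconstruction probabilities, same shape and dimnames
#'   as the input.
#' @export
reconstruct <- function(model, data) {
  stopifnot(is(model, "DeepAutoencoder"))
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  fw <- .ae_forward(model@rbms, X)
  out <- fw$ds[[1L]]
  dimnames(out) <- dimnames(X)
  out
}

#' Reconstruction error
#'
#' The reporting convention is the per-sample gene-summed error, averaged
#' over samples: with squared error, `mean_s sum_g (x_gs - r_gs)^2` (so the
#' magnitude scales with the number of genes retained, as in full-scale
#' reports of order 150 over 2228 genes). `"cross-entropy"` uses the
#' per-cell Bernoulli deviance instead.
#'
#' @param data binary matrix (or `SummarizedExperiment`).
#' @param recon matrix of reconstruction probabilities, same shape.
#' @param method `"squared"` (default) or `"cross-entropy"`.
#' @return A single number.
#' @examples
#' reconstructionError(matrix(1, 10, 3), matrix(0.5, 10, 3))  # 2.5
#' @export
reconstructionError <- function(data, recon,
                                method = c("squared", "cross-entropy")) {
  method <- match.arg(method)
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  if (!identical(dim(X), dim(recon)))
    stop("'data' and 'recon' must have identical dimensions")
  if (method == "squared") {
    mean(colSums((X - recon)^2))
  } else {
    eps <- 1e-12
    r <- pmin(pmax(recon, eps), 1 - eps)
    mean(colSums(-(X * log(r) + (1 - X) * log(1 - r))))
  }
}
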