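#' Training hyperparameters for (sparse) RBM learning
#'
#' Contrastive-divergence settings shared by single-RBM training and greedy
#' stack pretraining. The sparsity penalty adds
#' `lambda * sum_j (p - qbar_j)^2` to the minimized objective, where
#' `qbar_j` is the batch-mean conditional activation of hidden unit j; its
#' gradient is applied to hidden biases and weights.
#'
#' @param learningRate step size (> 0).
#' @param momentum initial momentum coefficient.
#' @param momentumFinal momentum after `momentumSwitch` epochs (common
#'   0.5 -> 0.9 schedule).
#' @param momentumSwitch epoch at which momentum switches.
#' @param nEpochs passes over the data.
#' @param batchSize mini-batch size.
#' @param cdSteps Gibbs alternations for the negative phase (CD-k);
#'   default 1.
#' @param weightDecay L2 penalty on weights.
#' @param sparsityTarget target mean activation p of hidden units, in
#'   \[0, 1\].
#' @param sparsityLambda regularization constant lambda (>= 0); 0 disables
#'   the penalty (dense model).
#' @param seed integer seed; all Gibbs sampling and batch shuffling derive
#'   from it, so training is deterministic.
#' @return A validated list of class `"trainParams"`.
#' @export
trainParams <- function(learningRate = 0.1, momentum = 0.5,
                        momentumFinal = 0.9, momentumSwitch = 5L,
                        nEpochs = 30L, batchSize = 100L, cdSteps = 1L,
                        weightDecay = 2e-4, sparsityTarget = 0.1,
                        sparsityLambda = 0, seed = 1L) {
  if (learningRate < 0) stop("'learningRate' must be >= 0")
  if (sparsityTarget < 0 || sparsityTarget > 1)
    stop("'sparsityTarget' must be in [0, 1]")
  if (sparsityLambda < 0) stop("'sparsityLambda' must be >= 0")
  if (cdSteps < 1) stop("'cdSteps' must be >= 1")
  structure(list(learningRate = learningRate, momentum = momentum,
                 momentumFinal = momentumFinal,
                 momentumSwitch = as.integer(momentumSwitch),
                 nEpochs = as.integer(nEpochs),
                 batchSize = as.integer(batchSize),
                 cdSteps = as.integer(cdSteps), weightDecay = weightDecay,
                 sparsityTarget = sparsityTarget,
                 sparsityLambda = sparsityLambda, seed = seed),
            class = "trainParams")
}

#' Construct an RBM
#'
#' @param W visible x hidden weight matrix.
#' @param a visible bias vector (length `nrow(W)`).
#' @param b hidden bias vector (length `ncol(W)`).
#' @return An [RBM] object.
#' @export
rbm <- function(W, a = numeric(nrow(W)), b = numeric(ncol(W))) {
  new("RBM", W = as.matrix(W), a = as.numeric(a), b = as.numeric(b))
}

.check_state <- function(x, len, what) {
  if (length(x) != len)
    stop(sprintf("'%s' has length %d, expected %d", what, length(x), len))
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must be a binary (0/1) vector", what))
  as.numeric(x)
}

#' RBM energy of a joint state
#'
#' `E(v, h) = -a'v - b'h - v'Wh`: low energy means high joint probability
#' under the Boltzmann distribution.
#'
#' @param v binary visible state (length D).
#' @param h binary hidden state (length F).
#' @param params an [RBM].
#' @return A single number.
#' @examples
#' r <- rbm(matrix(0.2), a = 0.5, b = 0.3)
#' energy(1, 1, r)  # -1
#' @export
energy <- function(v, h, params) {
  stopifnot(is(params, "RBM"))
  v <- .check_state(v, nrow(params@W), "v")
  h <- .check_state(h, ncol(params@W), "h")
  -sum(params@a * v) - sum(params@b * h) - drop(v %*% params@W %*% h)
}

#' Conditional activation probabilities of an RBM
#'
#' `hiddenConditional` returns `Pr(h_j = 1 | v) = sigma(b_j + sum_i W_ij v_i)`
#' for each hidden unit; `visibleConditional` the mirrored
#' `Pr(v_i = 1 | h) = sigma(a_i + sum_j W_ij h_j)`. Inputs may be a single
#' state vector or a matrix with one state per column (columns may hold
#' expected activations in \[0,1\] for mean-field propagation).
#'
#' @param params an [RBM].
#' @param v visible states: length-D vector or D x n matrix.
#' @param h hidden states: length-F vector or F x n matrix.
#' @return Probability vector (or matrix, one column per input column).
#' @examples
#' r <- rbm(matrix(1), a = 0, b = 0)
#' hiddenConditional(r, 1)  # sigma(1) = 0.731...
#' @export
hiddenConditional <- function(params, v) {
  stopifnot(is(params, "RBM"))
  D <- nrow(params@W)
  if (is.matrix(v)) {
    if (nrow(v) != D) stop(sprintf("'v' has %d rows, expected %d", nrow(v), D))
    sigmoid(crossprod(params@W, v) + params@b)
  } else {
    if (length(v) != D)
      stop(sprintf("'v' has length %d, expected %d", length(v), D))
    drop(sigmoid(crossprod(params@W, v) + params@b))
  }
}

#' @rdname hiddenConditional
#' @export
visibleConditional <- function(params, h) {
  stopifnot(is(params, "RBM"))
  F <- ncol(params@W)
  if (is.matrix(h)) {
    if (nrow(h) != F) stop(sprintf("'h' has %d rows, expected %d", nrow(h), F))
    sigmoid(params@W %*% h + params@a)
  } else {
    if (length(h) != F)
      stop(sprintf("'h' has length %d, expected %d", length(h), F))
    drop(sigmoid(params@W %*% h + params@a))
  }
}

#' Exact joint distribution of a small RBM by enumeration
#'
#' Enumerates all `2^(D+F)` joint states, computes `exp(-E)/Z` and the
#' partition function `Z`. Guarded at `D + F <= 20`; intended as an exact
#' oracle for testing conditionals, likelihoods and gradients on small
#' models.
#'
#' @param params an [RBM] with `D + F <= 20`.
#' @return A list with `v` (2^(D+F) x D state matrix), `h` (x F), `prob`
#'   (joint probabilities, summing to 1), and `Z`.
#' @export
exactJoint <- function(params) {
  stopifnot(is(params, "RBM"))
  D <- nrow(params@W); F <- ncol(params@W)
  if (D + F > 20L)
    stop("exactJoint enumerates 2^(D+F) states and refuses D + F > 20 (got ",
         D + F, ")")
  bits <- function(n) {
    if (n == 0L) return(matrix(0, 1, 0))
    g <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    dimnames(g) <- NULL
    g
  }
  V <- bits(D); H <- bits(F)
  nv <- nrow(V); nh <- nrow(H)
  ## negative energy for every (v, h) pair: rows index v-states, cols h-states
  negE <- outer(drop(V %*% params@a), drop(H %*% params@b), `+`) +
    (V %*% params@W) %*% t(H)
  w <- exp(negE)
  Z <- sum(w)
  iv <- rep(seq_len(nv), times = nh)
  ih <- rep(seq_len(nh), each = nv)
  list(v = V[iv, , drop = FALSE], h = H[ih, , drop = FALSE],
       prob = as.vector(w[cbind(iv, ih)]) / Z, Z = Z)
}

#' Sparsity penalty of a batch
#'
#' The unscaled penalty `sum_j (p - qbar_j)^2` where `qbar_j` is the mean
#' over the batch of `Pr(h_j = 1 | v)`; the caller multiplies by lambda.
#'
#' @param params an [RBM].
#' @param batch D x B binary matrix (one sample per column), non-empty.
#' @param p sparsity target.
#' @return A single number.
#' @export
sparsityPenalty <- function(params, batch, p) {
  stopifnot(is(params, "RBM"))
  if (!is.matrix(batch) || ncol(batch) == 0L)
    stop("'batch' must be a non-empty matrix")
  q <- hiddenConditional(params, batch)
  sum((p - rowMeans(q))^2)
}

## One CD-k step. Returns list(rbm, velocity, recon_err).
## Positive phase uses conditional means on the data; the negative chain
## samples hidden states, with means on the final alternation (standard
## CD practice). The sparsity-penalty gradient is applied to b and W.
.cd_step <- function(params, batch, hyper, velocity, momentum) {
  W <- params@W; a <- params@a; b <- params@b
  B <- ncol(batch)
  q <- sigmoid(crossprod(W, batch) + b)           # F x B
  H <- (q > matrix(runif(length(q)), nrow(q)))  * 1
  for (t in seq_len(hyper$cdSteps)) {
    vprob <- sigmoid(W %*% H + a)                 # D x B
    vs <- if (t < hyper$cdSteps)
      (vprob > matrix(runif(length(vprob)), nrow(vprob))) * 1 else vprob
    qn <- sigmoid(crossprod(W, vs) + b)
    if (t < hyper$cdSteps)
      H <- (qn > matrix(runif(length(qn)), nrow(qn))) * 1
  }
  gW <- (batch %*% t(q) - vs %*% t(qn)) / B - hyper$weightDecay * W
  ga <- rowMeans(batch - vs)
  gb <- rowMeans(q - qn)
  if (hyper$sparsityLambda > 0) {
    qbar <- rowMeans(q)
    s <- q * (1 - q)                              # d qbar / d preactivation
    cj <- -2 * hyper$sparsityLambda * (hyper$sparsityTarget - qbar) / B
    gb <- gb - cj * rowSums(s)
    gW <- gW - batch %*% t(s * cj)
  }
  velocity$W <- momentum * velocity$W + hyper$learningRate * gW
  velocity$a <- momentum * velocity$a + hyper$learningRate * ga
  velocity$b <- momentum * velocity$b + hyper$learningRate * gb
  params@W <- W + velocity$W
  params@a <- a + velocity$a
  params@b <- b + velocity$b
  list(rbm = params,
       velocity = velocity,
       err = sum((batch - sigmoid(params@W %*% q + params@a))^2) / B)
}

#' One contrastive-divergence update
#'
#' Applies a single CD-k gradient step (positive phase from the data
#' conditionals, negative phase from `cdSteps` Gibbs alternations) plus the
#' sparsity-penalty gradient, on one mini-batch. Deterministic given
#' `hyper$seed`. Momentum is not carried across calls here; [trainRBM()]
#' runs the full momentum schedule.
#'
#' @param params an [RBM].
#' @param batch D x B binary matrix, one sample per column.
#' @param hyper a [trainParams()] list.
#' @return The updated [RBM].
#' @export
cdUpdate <- function(params, batch, hyper) {
  stopifnot(is(params, "RBM"), inherits(hyper, "trainParams"))
  if (!is.matrix(batch) || nrow(batch) != nrow(params@W))
    stop(sprintf("'batch' must be a matrix with %d rows", nrow(params@W)))
  .check_unit_interval(batch, "batch")
  vel <- list(W = matrix(0, nrow(params@W), ncol(params@W)),
              a = numeric(nrow(params@W)), b = numeric(ncol(params@W)))
  withSeed(hyper$seed, .cd_step(params, batch, hyper, vel, momentum = 0)$rbm)
}

#' Train one (sparse) RBM by contrastive divergence
#'
#' Mini-batch CD-k with momentum, weight decay and the hidden-activation
#' sparsity penalty. Weights are initialised Normal(0, 0.01), biases at
#' zero. Batch order is reshuffled every epoch; everything is deterministic
#' given `hyper$seed`.
#'
#' @param data D x n binary matrix (genes x samples) or
#'   `SummarizedExperiment` with a `"binary"` assay.
#' @param nHidden number of hidden units.
#' @param hyper a [trainParams()] list.
#' @param init optional [RBM] to continue training from (warm start, e.g.
#'   for a learning-rate schedule); its shape must match.
#' @return An [RBM]; the per-epoch mean reconstruction error trace is
#'   attached as `attr(, "errorTrace")`.
#' @export
trainRBM <- function(data, nHidden, hyper = trainParams(), init = NULL) {
  m <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  ## upper stack layers train on expected activations, so [0,1] is allowed
  .check_unit_interval(m, "training data")
  if (nHidden < 1) stop("'nHidden' must be >= 1")
  D <- nrow(m); n <- ncol(m)
  withSeed(hyper$seed, {
    params <- if (!is.null(init)) {
      stopifnot(is(init, "RBM"), nrow(init@W) == D, ncol(init@W) == nHidden)
      init
    } else {
      ## visible biases start at the empirical log-odds of each gene being
      ## on, so weights model covariance rather than base rates
      pv <- pmin(pmax(rowMeans(m), 1e-3), 1 - 1e-3)
      new("RBM", W = matrix(rnorm(D * nHidden, 0, 0.01), D, nHidden),
          a = log(pv / (1 - pv)), b = numeric(nHidden))
    }
    vel <- list(W = matrix(0, D, nHidden), a = numeric(D),
                b = numeric(nHidden))
    trace <- numeric(hyper$nEpochs)
    for (ep in seq_len(hyper$nEpochs)) {
      mom <- if (ep > hyper$momentumSwitch) hyper$momentumFinal
             else hyper$momentum
      ord <- sample.int(n)
      starts <- seq(1L, n, by = hyper$batchSize)
      errs <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + hyper$batchSize - 1L, n)]
        st <- .cd_step(params, m[, idx, drop = FALSE], hyper, vel, mom)
        params <- st$rbm; vel <- st$velocity; errs[bi] <- st$err
      }
      trace[ep] <- mean(errs)
    }
    attr(params, "errorTrace") <- trace
    params
  })
}
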