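## NNDSVD initialisation (Boutsidis & Gallopoulos): deterministic
## SVD-based non-negative starting point for multiplicative updates.
.nndsvd <- function(V, rank, eps = 1e-9) {
  sv <- svd(V, nu = rank, nv = rank)
  W <- matrix(0, nrow(V), rank)
  H <- matrix(0, rank, ncol(V))
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (rank > 1L) for (j in 2:rank) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npn <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nnn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npn >= nnn) {
      W[, j] <- sqrt(sv$d[j] * npn) * up / max(sqrt(sum(up^2)), eps)
      H[j, ] <- sqrt(sv$d[j] * npn) * vp / max(sqrt(sum(vp^2)), eps)
    } else {
      W[, j] <- sqrt(sv$d[j] * nnn) * un / max(sqrt(sum(un^2)), eps)
      H[j, ] <- sqrt(sv$d[j] * nnn) * vn / max(sqrt(sum(vn^2)), eps)
    }
  }
  mean_v <- mean(V)
  W[W < eps] <- mean_v * eps
  H[H < eps] <- mean_v * eps
  list(W = W, H = H)
}

#' Non-negative matrix factorization baseline
#'
#' Factorizes a non-negative gene x sample matrix `V ~ W %*% H` (basis W,
#' coefficients H; the columns of W are "metagenes") by multiplicative
#' updates minimizing the Frobenius reconstruction error, from a
#' deterministic SVD-based (NNDSVD) starting point (`init = "random"`
#' gives a seeded random start instead). A binary expression matrix is a
#' valid input.
#'
#' @param V non-negative gene x sample matrix.
#' @param rank number of metagenes (<= both dimensions).
#' @param seed seed for `init = "random"`.
#' @param maxIter maximum multiplicative updates (default 500).
#' @param tol relative change in error below which iteration stops.
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @return A list of class `"nmfFactors"`: `W` (gene x rank), `H`
#'   (rank x sample), `rank`, `error` (final Frobenius error) and `trace`.
#' @export
nmfFactorize <- function(V, rank, seed = 1L, maxIter = 500L, tol = 1e-9,
                         init = c("nndsvd", "random")) {
  init <- match.arg(init)
  V <- .as_gene_matrix(V)
  if (any(V < 0)) stop("'V' must be non-negative")
  if (rank > min(dim(V))) stop("'rank' must not exceed either dimension of 'V'")
  eps <- .Machine$double.eps
  st <- if (init == "nndsvd") .nndsvd(V, rank)
        else withSeed(seed, list(W = matrix(runif(nrow(V) * rank), ncol = rank),
                                 H = matrix(runif(rank * ncol(V)), nrow = rank)))
  W <- st$W; H <- st$H
  errs <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((V - W %*% H)^2))
    errs <- c(errs, err)
    if (is.finite(prev) && prev - err < tol * max(prev, eps)) break
    prev <- err
  }
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  colnames(W) <- rownames(H) <- sprintf("MG%02d", seq_len(rank))
  structure(list(W = W, H = H, rank = rank, error = err, trace = errs),
            class = "nmfFactors")
}

#' Consensus clustering of samples by subsampled reclustering
#'
#' Repeatedly subsamples the samples, clusters each subsample with the base
#' algorithm (partition around medoids or k-means), and records for every
#' sample pair the fraction of co-clusterings among co-samplings. Final
#' labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at `k`.
#'
#' @param features sample x feature matrix (samples are the objects
#'   clustered; transpose gene x sample matrices first).
#' @param k number of clusters (>= 2).
#' @param base `"pam"` or `"kmeans"`.
#' @param nResamples number of subsampling rounds (default 100).
#' @param subsampleFraction fraction of samples per round (default 0.8).
#' @param seed seed for subsampling (and k-means starts).
#' @return A list of class `"consensusResult"`: `consensus` (sample x
#'   sample matrix in \[0,1\], symmetric, unit diagonal), `labels` (final
#'   cluster labels), `k`, `base`, `settings`.
#' @export
consensusCluster <- function(features, k, base = c("pam", "kmeans"),
                             nResamples = 100L, subsampleFraction = 0.8,
                             seed = 1L) {
  base <- match.arg(base)
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2L) stop("'k' must be >= 2")
  if (k > n) stop("'k' must not exceed the number of samples")
  if (nResamples < 2L) stop("'nResamples' must be >= 2")
  if (is.null(rownames(features)))
    rownames(features) <- .default_ids(n, "S")
  withSeed(seed, {
    co <- matrix(0, n, n)     # co-clustered counts
    tog <- matrix(0, n, n)    # co-sampled counts
    m <- max(k + 1L, round(subsampleFraction * n))
    for (r in seq_len(nResamples)) {
      idx <- sort(sample.int(n, m))
      sub <- features[idx, , drop = FALSE]
      lab <- if (base == "pam")
        cluster::pam(sub, k, cluster.only = TRUE, pamonce = 5)
      else kmeans(sub, centers = k, nstart = 5)$cluster
      tog[idx, idx] <- tog[idx, idx] + 1
      same <- outer(lab, lab, `==`) * 1
      co[idx, idx] <- co[idx, idx] + same
    }
    cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(rownames(features), rownames(features))
    hc <- hclust(as.dist(1 - cons), method = "average")
    labels <- cutree(hc, k = k)
    structure(list(consensus = cons, labels = labels, k = k, base = base,
                   settings = list(nResamples = nResamples,
                                   subsampleFraction = subsampleFraction,
                                   seed = seed)),
              class = "consensusResult")
  })
}

#' Within-minus-between cluster separation of a consensus matrix
#'
#' Mean consensus over within-cluster sample pairs minus the mean over
#' between-cluster pairs; higher means cleaner, more stable clusters.
#'
#' @param result a `consensusResult` from [consensusCluster()].
#' @return A single number.
#' @export
separationScore <- function(result) {
  cons <- result$consensus
  lab <- result$labels
  same <- outer(lab, lab, `==`)
  off <- upper.tri(cons)
  mean(cons[off & same]) - mean(cons[off & !same])
}

#' Consensus-cluster samples under alternative representations
#'
#' Runs [consensusCluster()] on (i) the raw binary gene x sample matrix,
#' (ii) the NMF coefficient (metagene x sample) matrix, and (iii) the
#' expected hidden states of a chosen autoencoder layer, and reports the
#' separation score of each representation (and, when planted labels are
#' supplied, the adjusted Rand index against them).
#'
#' @param data binary gene x sample matrix or `SummarizedExperiment`.
#' @param model a trained [DeepAutoencoder].
#' @param nmfRank rank of the NMF baseline.
#' @param k number of clusters.
#' @param layer autoencoder layer used for the hidden representation.
#' @param truth optional vector of planted sample group labels.
#' @param ... further arguments passed to [consensusCluster()].
#' @return A list of class `"representationComparison"`: per-representation
#'   `consensusResult`s, a `scores` data.frame, and `ari` when `truth` was
#'   given.
#' @export
compareRepresentations <- function(data, model, nmfRank, k, layer = 1L,
                                   truth = NULL, ...) {
  X <- if (is(data, "SummarizedExperiment")) .as_gene_matrix(data, "binary")
       else .as_gene_matrix(data)
  reps <- list(
    genes = t(X),
    nmf = t(nmfFactorize(X, nmfRank)$H),
    hidden = t(inferHidden(model, X, layer)))
  results <- lapply(reps, consensusCluster, k = k, ...)
  scores <- data.frame(
    representation = names(results),
    separation = vapply(results, separationScore, numeric(1)),
    stringsAsFactors = FALSE)
  ari <- NULL
  if (!is.null(truth)) {
    ari <- vapply(results, function(r)
      mclust::adjustedRandIndex(r$labels, truth), numeric(1))
    scores$ari <- ari
  }
  structure(list(results = results, scores = scores, ari = ari),
            class = "representationComparison")
}

#' Cluster-by-cluster correspondence between two labelings
#'
#' For every pair of clusters (one from each labeling of the same samples),
#' tests the overlap of their members with the upper-tail hypergeometric
#' test over the sample universe and BH-adjusts across all pairs. Also
#' returns the binary sample x cluster membership matrices (a sample's
#' value is 1 in the column of its cluster).
#'
#' @param labelsA,labelsB cluster label vectors over the same samples.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return A list of class `"clusterCorrespondence"`: `pvalues`, `adjusted`,
#'   `significant` (clustersA x clustersB matrices), `membershipA`,
#'   `membershipB`.
#' @export
clusterCorrespondence <- function(labelsA, labelsB, alpha = 0.05) {
  if (length(labelsA) != length(labelsB))
    stop("labelings must cover the same samples")
  n <- length(labelsA)
  samples <- if (!is.null(names(labelsA))) names(labelsA)
             else .default_ids(n, "S")
  setsA <- split(samples, labelsA)
  setsB <- split(samples, labelsB)
  em <- .enrichment_matrix(setsA, setsB, samples)
  adj <- matrix(p.adjust(em$p, method = "BH"), nrow(em$p), ncol(em$p),
                dimnames = dimnames(em$p))
  memb <- function(sets) {
    m <- matrix(0L, n, length(sets), dimnames = list(samples, names(sets)))
    for (j in seq_along(sets)) m[sets[[j]], j] <- 1L
    m
  }
  structure(list(pvalues = em$p, adjusted = adj,
                 significant = adj <= alpha, overlap = em$overlap,
                 membershipA = memb(setsA), membershipB = memb(setsB)),
            class = "clusterCorrespondence")
}
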