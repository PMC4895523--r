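## Independent brute-force oracles, written from the model definitions and
## deliberately not sharing code paths with the package internals.

## Enumerate all joint states of a small RBM with explicit scalar loops.
enum_rbm <- function(W, a, b) {
  D <- length(a); F <- length(b)
  vs <- as.matrix(expand.grid(rep(list(0:1), D)))
  hs <- as.matrix(expand.grid(rep(list(0:1), F)))
  dimnames(vs) <- dimnames(hs) <- NULL
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(hs))) {
    v <- vs[i, ]; h <- hs[j, ]
    E <- 0
    for (d in seq_len(D)) E <- E - a[d] * v[d]
    for (f in seq_len(F)) E <- E - b[f] * h[f]
    for (d in seq_len(D)) for (f in seq_len(F)) E <- E - v[d] * h[f] * W[d, f]
    k <- k + 1L
    rows[[k]] <- list(v = v, h = h, negE = unname(-E))
  }
  w <- exp(vapply(rows, `[[`, numeric(1), "negE"))
  Z <- sum(w)
  list(rows = rows, prob = w / Z, Z = Z,
       v = do.call(rbind, lapply(rows, `[[`, "v")),
       h = do.call(rbind, lapply(rows, `[[`, "h")))
}

## Conditional Pr(h_j = 1 | v) from the enumeration table.
enum_hidden_cond <- function(tab, v) {
  sel <- apply(tab$v, 1L, function(x) all(x == v))
  vapply(seq_len(ncol(tab$h)), function(j)
    sum(tab$prob[sel & tab$h[, j] == 1]) / sum(tab$prob[sel]), numeric(1))
}

enum_visible_cond <- function(tab, h) {
  sel <- apply(tab$h, 1L, function(x) all(x == h))
  vapply(seq_len(ncol(tab$v)), function(i)
    sum(tab$prob[sel & tab$v[, i] == 1]) / sum(tab$prob[sel]), numeric(1))
}

## Exact log-likelihood gradient of an RBM on data X (columns = samples):
## positive phase from the data conditionals, negative phase from the
## enumerated model expectations.
enum_loglik_grad <- function(r, X) {
  tab <- enum_rbm(r@W, r@a, r@b)
  EW <- t(tab$v) %*% (tab$prob * tab$h)
  Ea <- colSums(tab$prob * tab$v)
  Eb <- colSums(tab$prob * tab$h)
  q <- 1 / (1 + exp(-(t(r@W) %*% X + r@b)))
  list(W = X %*% t(q) / ncol(X) - EW,
       a = rowMeans(X) - Ea,
       b = rowMeans(q) - Eb)
}

## Mean exact log-likelihood of binary columns of X under a small RBM.
enum_loglik <- function(r, X) {
  tab <- enum_rbm(r@W, r@a, r@b)
  idx <- apply(tab$v, 1L, function(v) sum(v * 2^(seq_along(v) - 1L)))
  pv <- tapply(tab$prob, idx, sum)
  xidx <- apply(X, 2L, function(v) sum(v * 2^(seq_along(v) - 1L)))
  mean(log(pv[as.character(xidx)]))
}

## Central finite-difference check of the full unrolled-network gradient:
## returns ||fd - analytic|| / ||fd|| over every parameter of every layer.
fd_gradient_check <- function(m, x, g, eps = 1e-6,
                              sparsityTarget = 0.1, sparsityLambda = 0) {
  fds <- c(); ans <- c()
  loss_of <- function(mm)
    autoencoderGradient(mm, x, sparsityTarget, sparsityLambda)$loss
  for (k in seq_along(m@rbms)) {
    W <- m@rbms[[k]]@W
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      mp <- m; mp@rbms[[k]]@W[i, j] <- W[i, j] + eps
      mn <- m; mn@rbms[[k]]@W[i, j] <- W[i, j] - eps
      fds <- c(fds, (loss_of(mp) - loss_of(mn)) / (2 * eps))
      ans <- c(ans, g$grads[[k]]$W[i, j])
    }
    for (i in seq_along(m@rbms[[k]]@a)) {
      mp <- m; mp@rbms[[k]]@a[i] <- mp@rbms[[k]]@a[i] + eps
      mn <- m; mn@rbms[[k]]@a[i] <- mn@rbms[[k]]@a[i] - eps
      fds <- c(fds, (loss_of(mp) - loss_of(mn)) / (2 * eps))
      ans <- c(ans, g$grads[[k]]$a[i])
    }
    for (i in seq_along(m@rbms[[k]]@b)) {
      mp <- m; mp@rbms[[k]]@b[i] <- mp@rbms[[k]]@b[i] + eps
      mn <- m; mn@rbms[[k]]@b[i] <- mn@rbms[[k]]@b[i] - eps
      fds <- c(fds, (loss_of(mp) - loss_of(mn)) / (2 * eps))
      ans <- c(ans, g$grads[[k]]$b[i])
    }
  }
  sqrt(sum((fds - ans)^2)) / sqrt(sum(fds^2))
}

random_rbm <- function(D, F, seed, scale = 0.8) {
  set.seed(seed)
  rbm(matrix(rnorm(D * F, 0, scale), D, F),
      a = rnorm(D, 0, scale), b = rnorm(F, 0, scale))
}

## Small planted compendium used across tests.
tiny_compendium <- function(seed = 1, nSamples = 60, ...) {
  cfg <- networkConfig(nGenes = 60, nTFs = 6, nPathways = 3,
                       targetsPerTF = c(5, 8), tfsPerPathway = c(2, 3),
                       seed = seed, ...)
  net <- generateNetwork(cfg)
  se <- simulateCompendium(net, cfg, nSamples)
  list(cfg = cfg, net = net, se = se)
}
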