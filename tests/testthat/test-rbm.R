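test_that("energy matches its closed form and the enumeration oracle", {
  r0 <- rbm(matrix(0.2), a = 0.5, b = 0.3)
  expect_equal(energy(0, 0, r0), 0)
  expect_equal(energy(1, 1, r0), -1.0)
  expect_error(energy(c(1, 0), 1, r0), "length")
  r <- random_rbm(3, 2, seed = 21)
  tab <- enum_rbm(r@W, r@a, r@b)
  ## sum of exp(-E) over all 2^5 states equals the partition function
  Zpkg <- exactJoint(r)$Z
  expect_equal(tab$Z, Zpkg, tolerance = 1e-12)
  ## energies agree state by state
  for (k in sample(length(tab$prob), 8)) {
    expect_equal(-energy(tab$v[k, ], tab$h[k, ], r), tab$rows[[k]]$negE,
                 tolerance = 1e-12)
  }
})

test_that("conditionals reduce to the logistic closed form", {
  rz <- rbm(matrix(0, 4, 3))
  expect_equal(hiddenConditional(rz, c(1, 0, 1, 0)), rep(0.5, 3))
  expect_equal(visibleConditional(rz, c(1, 1, 0)), rep(0.5, 4))
  r1 <- rbm(matrix(1), a = 0, b = 0)
  expect_equal(hiddenConditional(r1, 1), 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(visibleConditional(r1, 1), 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_error(hiddenConditional(r1, c(1, 0)), "length")
})

test_that("conditionals agree with conditioning the enumerated joint to 1e-10", {
  for (s in 1:12) {
    D <- sample(2:5, 1); F <- sample(1:4, 1)
    r <- random_rbm(D, F, seed = 300 + s)
    tab <- enum_rbm(r@W, r@a, r@b)
    v <- rbinom(D, 1, 0.5)
    expect_lt(max(abs(hiddenConditional(r, v) - enum_hidden_cond(tab, v))), 1e-10)
    h <- rbinom(F, 1, 0.5)
    expect_lt(max(abs(visibleConditional(r, h) - enum_visible_cond(tab, h))), 1e-10)
  }
})

test_that("exactJoint normalizes, matches the analytic marginal, and guards size", {
  rz <- rbm(matrix(0))
  ej <- exactJoint(rz)
  expect_equal(ej$prob, rep(0.25, 4))
  r <- random_rbm(4, 3, seed = 33)
  ej <- exactJoint(r)
  expect_equal(sum(ej$prob), 1, tolerance = 1e-12)
  ## marginal Pr(v) via the product-over-hidden-units formula
  v <- c(1, 0, 1, 1)
  sel <- apply(ej$v, 1, function(x) all(x == v))
  pv <- sum(ej$prob[sel])
  analytic <- exp(sum(r@a * v)) *
    prod(1 + exp(r@b + colSums(r@W * v))) / ej$Z
  expect_equal(pv, analytic, tolerance = 1e-12)
  expect_error(exactJoint(rbm(matrix(0, 15, 15))), "refuses")
})

test_that("sparsityPenalty equals its definition", {
  r <- rbm(matrix(0), a = 0, b = log(0.6 / 0.4))  # one unit, E[h] = 0.6
  expect_equal(sparsityPenalty(r, matrix(0, 1, 1), p = 0.1), 0.25,
               tolerance = 1e-9)
  r2 <- random_rbm(5, 3, seed = 44)
  set.seed(45)
  batch <- matrix(rbinom(5 * 7, 1, 0.4), 5, 7)
  q <- 1 / (1 + exp(-(t(r2@W) %*% batch + r2@b)))
  expect_equal(sparsityPenalty(r2, batch, 0.2), sum((0.2 - rowMeans(q))^2),
               tolerance = 1e-12)
  ## zero when every unit's mean activation is exactly p
  expect_equal(sparsityPenalty(rbm(matrix(0, 2, 2)),
                               matrix(0, 2, 3), p = 0.5), 0)
  expect_error(sparsityPenalty(r2, matrix(numeric(0), 5, 0), 0.1), "non-empty")
})

test_that("a zero learning rate leaves parameters unchanged", {
  r <- random_rbm(4, 2, seed = 55)
  set.seed(56)
  batch <- matrix(rbinom(16, 1, 0.5), 4, 4)
  hy <- trainParams(learningRate = 0, seed = 9)
  r2 <- cdUpdate(r, batch, hy)
  expect_identical(r2@W, r@W)
  expect_identical(r2@a, r@a)
  expect_identical(r2@b, r@b)
})

test_that("with strong penalty, p = 0 and all-zero data, hidden biases descend", {
  r <- rbm(matrix(0, 3, 2), a = rep(0, 3), b = c(0.5, 0.2))
  hy <- trainParams(learningRate = 0.1, sparsityTarget = 0,
                    sparsityLambda = 50, weightDecay = 0, seed = 2)
  batch <- matrix(0, 3, 10)
  cur <- r
  bs <- r@b
  for (i in 1:5) {
    cur <- cdUpdate(cur, batch, hy)
    expect_true(all(cur@b < bs))
    bs <- cur@b
  }
  ## numerical gradient of the penalty confirms the descent direction
  p0 <- sparsityPenalty(r, batch, 0)
  eps <- 1e-6
  rp <- r; rp@b[1] <- rp@b[1] + eps
  gnum <- (sparsityPenalty(rp, batch, 0) - p0) / eps
  expect_gt(gnum, 0)  # increasing b increases the penalty, so b must fall
})

test_that("averaged CD-1 updates align with the exact likelihood gradient", {
  ## scaled-down version of the gradient-fidelity check (4 visible, 2 hidden)
  gen <- random_rbm(4, 2, seed = 77, scale = 1)
  tab <- enum_rbm(gen@W, gen@a, gen@b)
  idx <- apply(tab$v, 1, function(v) sum(v * 2^(seq_along(v) - 1)))
  pv <- tapply(tab$prob, idx, sum)
  states <- unique(tab$v)
  set.seed(78)
  pos <- 0L
  for (t in 1:200) {
    r <- random_rbm(4, 2, seed = 1000 + t, scale = 0.5)
    pick <- sample(nrow(states), 64, replace = TRUE,
                   prob = pv[as.character(apply(states, 1, function(v)
                     sum(v * 2^(seq_along(v) - 1))))])
    X <- t(states[pick, , drop = FALSE])
    g <- enum_loglik_grad(r, X)
    hy <- trainParams(learningRate = 1, momentum = 0, weightDecay = 0,
                      sparsityLambda = 0, seed = t)
    r2 <- cdUpdate(r, X, hy)
    upd <- c(r2@W - r@W, r2@a - r@a, r2@b - r@b)
    if (sum(upd * c(g$W, g$a, g$b)) > 0) pos <- pos + 1L
  }
  expect_gt(pos / 200, 0.9)
})

test_that("training with no penalty increases exact log-likelihood", {
  ## generator: two hidden causes, each switching on a block of three genes;
  ## its data are strongly dependent, so the independence starting point is
  ## clearly improvable and learning must capture the covariance
  gen <- rbm(cbind(c(rep(5, 3), rep(0, 3)), c(rep(0, 3), rep(5, 3))),
             a = rep(-2.5, 6), b = rep(-8, 2))
  tab <- enum_rbm(gen@W, gen@a, gen@b)
  idx <- apply(tab$v, 1, function(v) sum(v * 2^(seq_along(v) - 1)))
  pv <- tapply(tab$prob, idx, sum)
  states <- unique(tab$v)
  skey <- as.character(apply(states, 1, function(v)
    sum(v * 2^(seq_along(v) - 1))))
  for (s in 1:3) {
    set.seed(s)
    pick <- sample(nrow(states), 150, replace = TRUE, prob = pv[skey])
    X <- t(states[pick, , drop = FALSE])
    init <- trainRBM(X, 2, trainParams(nEpochs = 0, seed = s))
    hy50 <- trainParams(learningRate = 0.05, nEpochs = 50, batchSize = 25,
                        weightDecay = 0, sparsityLambda = 0, seed = s)
    m50 <- trainRBM(X, 2, hy50)
    expect_gt(enum_loglik(m50, X), enum_loglik(init, X))
  }
})

test_that("training is deterministic and the sparse model is sparser than the dense", {
  d <- tiny_compendium(seed = 31, nSamples = 120)
  X <- SummarizedExperiment::assay(
    binarizeExpression(d$se), "binary")
  hy <- trainParams(learningRate = 0.1, nEpochs = 40, batchSize = 30,
                    sparsityTarget = 0.1, sparsityLambda = 5, seed = 3)
  m1 <- trainRBM(X, 6, hy)
  m2 <- trainRBM(X, 6, hy)
  expect_identical(m1@W, m2@W)
  dense <- hy; dense$sparsityLambda <- 0
  mD <- trainRBM(X, 6, dense)
  expect_lt(mean(hiddenConditional(m1, X)), mean(hiddenConditional(mD, X)))
})
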