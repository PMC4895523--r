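test_that("effective weights multiply through the stack", {
  set.seed(1)
  x <- matrix(rbinom(5 * 20, 1, 0.4), 5, 20)
  m <- pretrainAutoencoder(x, c(4, 3, 2), trainParams(nEpochs = 2, batchSize = 10))
  expect_equal(unname(effectiveWeights(m, 1)), unname(m@rbms[[1]]@W))
  ## identity second layer leaves the layer-1 result unchanged
  m2 <- m
  m2@rbms[[2]]@W <- diag(4)[, 1:3] * 0
  m2@rbms[[2]]@W[1:3, 1:3] <- diag(3)
  ew2 <- effectiveWeights(m2, 2)
  expect_equal(unname(ew2), unname(m@rbms[[1]]@W %*% m2@rbms[[2]]@W))
  ## path-enumeration oracle on a 3-layer toy
  ew3 <- effectiveWeights(m, 3)
  W1 <- m@rbms[[1]]@W; W2 <- m@rbms[[2]]@W; W3 <- m@rbms[[3]]@W
  g <- 2; u <- 1
  pathSum <- 0
  for (i in seq_len(ncol(W1))) for (j in seq_len(ncol(W2)))
    pathSum <- pathSum + W1[g, i] * W2[i, j] * W3[j, u]
  expect_equal(unname(ew3[g, u]), pathSum, tolerance = 1e-12)
  expect_error(effectiveWeights(m, 4), "layer")
})

test_that("top-fraction thresholding keeps ceil(fraction * N) edges with stable ties", {
  W <- matrix(seq(0.01, 1, length.out = 100), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("u", 1:10)))
  gs <- thresholdTopFraction(W, 0.15)
  expect_identical(sum(lengths(gs$sets)), 15L)
  ## all-equal weights: ties broken by unit then gene index
  We <- matrix(1, 10, 10, dimnames = dimnames(W))
  gse <- thresholdTopFraction(We, 0.15)
  expect_identical(lengths(gse$sets)[1:2], c(u1 = 10L, u2 = 5L))
  expect_identical(gse$sets$u2, paste0("g", 1:5))
  expect_identical(thresholdTopFraction(We, 0.15)$sets, gse$sets)
  ## sort-and-slice oracle on random signed weights
  set.seed(5)
  Wr <- matrix(rnorm(60), 12, 5,
               dimnames = list(paste0("g", 1:12), paste0("u", 1:5)))
  gsr <- thresholdTopFraction(Wr, 0.2)
  ord <- order(-abs(Wr))[seq_len(ceiling(0.2 * 60))]
  expected <- split(rownames(Wr)[row(Wr)[ord]], colnames(Wr)[col(Wr)[ord]])
  for (u in names(expected))
    expect_setequal(gsr$sets[[u]], expected[[u]])
  ## per-unit scope keeps the same count in every column
  gspu <- thresholdTopFraction(Wr, 0.25, scope = "per_unit")
  expect_true(all(lengths(gspu$sets) == 3L))
  expect_error(thresholdTopFraction(Wr, 0))
})

test_that("hypergeometric overlap matches combinatorics and brute force", {
  u <- letters[1:10]
  expect_equal(hypergeometricOverlap(u[1:5], u[1:5], u), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeometricOverlap(u, u[1:4], u), 1)
  expect_equal(hypergeometricOverlap(character(0), u[1:4], u), 1)
  expect_error(hypergeometricOverlap(u[1:2], u[1:3], character(0)), "universe")
  ## brute force: enumerate all C(10, |A|) draws and count overlaps >= observed
  draws <- combn(10, 5)
  for (setB in list(u[1:4], u[3:9], u[1])) {
    for (setA in list(u[1:5], u[c(2, 4, 6, 8, 10)])) {
      bf <- mean(apply(draws, 2, function(d)
        length(intersect(u[d], setB)) >= length(intersect(setA, setB))))
      expect_equal(hypergeometricOverlap(setA, setB, u), bf, tolerance = 1e-12)
      expect_equal(hypergeometricOverlap(setA, setB, u),
                   hypergeometricOverlap(setB, setA, u), tolerance = 1e-12)
    }
  }
})

test_that("unit-TF mapping finds constructed hits and handles empty sets", {
  universe <- paste0("g", 1:50)
  tfs <- list(TFa = universe[1:10], TFb = universe[11:20], TFc = universe[21:30])
  assign <- structure(list(
    sets = list(u1 = universe[1:10], u2 = character(0)),
    universe = universe, fraction = 0.15, scope = "global"),
    class = "geneSetAssignment")
  mp <- mapUnitsToTFs(assign, tfs, alpha = 0.05)
  bh <- bestHits(mp)
  expect_identical(bh$tf[bh$unit == "u1"], "TFa")
  expect_true(bh$significant[bh$unit == "u1"])
  expect_false(any(mp@significant["u2", ]))
  expect_true(all(mp@pvalues["u2", ] == 1))
  expect_true(all(mp@adjusted >= mp@pvalues - 1e-12))
  ## significant-pair count is monotone in alpha
  n1 <- sum(mapUnitsToTFs(assign, tfs, alpha = 0.01)@significant)
  n2 <- sum(mapUnitsToTFs(assign, tfs, alpha = 0.2)@significant)
  expect_lte(n1, n2)
  ## one-to-one recovery bookkeeping
  rec <- oneToOneRecovery(mp)
  expect_equal(as.numeric(rec), 1 / 3)
  expect_identical(attr(rec, "recovered"), "TFa")
})

test_that("activity calls take each unit's top fraction with index tie-breaks", {
  set.seed(11)
  st <- matrix(runif(300), 3, 100,
               dimnames = list(paste0("u", 1:3), paste0("s", 1:100)))
  calls <- unitActivityCalls(st, 0.15)
  expect_true(all(rowSums(calls) == 15))
  for (u in 1:3) {
    expect_setequal(which(calls[u, ] == 1), order(-st[u, ])[1:15])
  }
  const <- matrix(0.4, 2, 100)
  cc <- unitActivityCalls(const, 0.15)
  expect_identical(unname(which(cc[1, ] == 1)), 1:15)
})

test_that("chi-square association reproduces the Pearson statistic", {
  even <- chisqAssociation(rep(c(1, 0), each = 10), rep(c(1, 0), 10))
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)
  perfect <- chisqAssociation(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
  expect_equal(perfect$statistic, 20, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    u <- rbinom(60, 1, 0.4); p <- rbinom(60, 1, 0.3)
    if (length(unique(u)) < 2 || length(unique(p)) < 2) next
    res <- chisqAssociation(u, p)
    O <- res$table
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
    expect_equal(res$p.value, stats::pchisq(res$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chisqAssociation(rep(1, 10), rbinom(10, 1, 0.5)), "degenerate")
})

test_that("generic annotation enrichment agrees with the TF mapping machinery", {
  universe <- paste0("g", 1:40)
  sets <- list(u1 = universe[1:8], u2 = universe[30:40])
  assign <- structure(list(sets = sets, universe = universe,
                           fraction = 0.15, scope = "global"),
                      class = "geneSetAssignment")
  ann <- list(A = universe[1:8], B = universe[9:16])
  tab <- annotateGeneSets(assign, ann, alpha = 0.05)
  expect_identical(tab$set[1], "A")
  expect_identical(tab$unit[1], "u1")
  mp <- mapUnitsToTFs(assign, ann, alpha = 0.05)
  expect_equal(sort(tab$p), sort(as.vector(mp@pvalues)), tolerance = 1e-12)
  ## disjoint annotations are never significant
  far <- list(Z = universe[17:24])
  tab2 <- annotateGeneSets(assign, far, alpha = 0.99)
  expect_false(any(tab2$p < 0.5))
})
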