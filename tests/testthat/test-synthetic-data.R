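test_that("generateNetwork respects sizes, ranges and determinism", {
  cfg <- networkConfig(nGenes = 200, nTFs = 20, nPathways = 5,
                       targetsPerTF = c(10, 15), tfsPerPathway = c(4, 5),
                       seed = 1)
  net <- generateNetwork(cfg)
  expect_length(tfIds(net), 20)
  expect_length(geneIds(net), 200)
  sizes <- lengths(tfTargets(net))
  expect_true(all(sizes >= 10 & sizes <= 15))
  expect_true(all(!duplicated(net@tfGene)))
  ## every TF regulated by at least one pathway when slots suffice
  expect_setequal(unique(net@pathwayTF$tf), tfIds(net))
  net2 <- generateNetwork(cfg)
  expect_identical(net@tfGene, net2@tfGene)
  expect_identical(net@pathwayTF, net2@pathwayTF)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(networkConfig(nTFs = 0), "nTFs")
  expect_error(networkConfig(pBackground = 1.5), "pBackground")
  expect_error(networkConfig(nGenes = 10, nTFs = 20), "nTFs")
  expect_error(networkConfig(deLogratioLocation = 1), "deLogratioLocation")
  expect_error(simulateCompendium(generateNetwork(networkConfig(seed = 1)),
                                  networkConfig(seed = 1), nSamples = 0),
               "nSamples")
})

test_that("simulateCompendium is deterministic given the seed", {
  d <- tiny_compendium(seed = 4)
  se2 <- simulateCompendium(d$net, d$cfg, 60)
  expect_identical(SummarizedExperiment::assay(d$se, "logRatio"),
                   SummarizedExperiment::assay(se2, "logRatio"))
  se3 <- simulateCompendium(d$net, d$cfg, 60, seed = 99)
  expect_false(identical(SummarizedExperiment::assay(d$se, "logRatio"),
                         SummarizedExperiment::assay(se3, "logRatio")))
})

test_that("deterministic limit: full response, no background marks exactly the planted targets", {
  cfg <- networkConfig(nGenes = 80, nTFs = 8, nPathways = 4,
                       pTFResponse = 1, pTargetResponse = 1, pBackground = 0,
                       deLogratioSd = 0.05, nullLogratioSd = 1e-4, seed = 5)
  net <- generateNetwork(cfg)
  se <- simulateCompendium(net, cfg, 25)
  bin <- SummarizedExperiment::assay(binarizeExpression(se), "binary")
  labs <- perturbedPathways(se)
  tt <- tfTargets(net)
  ptf <- pathwayTFs(net)
  for (s in seq_len(ncol(bin))) {
    tfs <- unique(unlist(ptf[labs[[s]]]))
    expected <- sort(unique(unlist(tt[tfs])))
    expect_identical(rownames(bin)[bin[, s] == 1], expected)
  }
})

test_that("zero response and zero background binarizes to an all-zero matrix", {
  cfg <- networkConfig(nGenes = 50, nTFs = 5, nPathways = 2,
                       pTargetResponse = 0, pBackground = 0,
                       nullLogratioSd = 1e-4, seed = 6)
  net <- generateNetwork(cfg)
  se <- simulateCompendium(net, cfg, 30)
  bin <- SummarizedExperiment::assay(binarizeExpression(se), "binary")
  expect_true(all(bin == 0))
})

test_that("background DE rate among non-target genes matches pBackground", {
  ## binomial oracle on binarized calls; tight DE magnitudes so essentially
  ## every planted background event clears the 3-fold cut
  cfg <- networkConfig(nGenes = 200, nTFs = 20, nPathways = 5,
                       pBackground = 0.01, deLogratioSd = 0.1, seed = 7)
  net <- generateNetwork(cfg)
  se <- simulateCompendium(net, cfg, 500)
  bin <- SummarizedExperiment::assay(binarizeExpression(se), "binary")
  nonTargets <- setdiff(geneIds(net), unique(net@tfGene$gene))
  expect_gt(length(nonTargets), 20)
  cells <- bin[nonTargets, ]
  phat <- mean(cells)
  se3 <- 3 * sqrt(0.01 * 0.99 / length(cells))
  expect_lt(abs(phat - 0.01), se3)
})

test_that("planted background-call rate is binomial at pBackground across seeds", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- networkConfig(nGenes = 100, nTFs = 10, nPathways = 3,
                         pBackground = 0.02, seed = s)
    net <- generateNetwork(cfg)
    se <- simulateCompendium(net, cfg, 60)
    de <- S4Vectors::metadata(se)$deCalls
    nonTargets <- setdiff(geneIds(net), unique(net@tfGene$gene))
    hits <- hits + sum(de[nonTargets, ])
    total <- total + length(nonTargets) * ncol(se)
  }
  expect_gt(stats::binom.test(hits, total, p = 0.02)$p.value, 0.001)
})

test_that("genes sharing a TF co-differential-express more than random pairs", {
  d <- tiny_compendium(seed = 8, nSamples = 250)
  bin <- SummarizedExperiment::assay(binarizeExpression(d$se), "binary")
  tt <- tfTargets(d$net)
  set.seed(42)
  sharedCor <- c(); randomCor <- c()
  for (rep in 1:120) {
    tf <- sample(names(tt), 1)
    pair <- sample(tt[[tf]], 2)
    g2 <- sample(geneIds(d$net), 2)
    cs <- suppressWarnings(cor(bin[pair[1], ], bin[pair[2], ]))
    cr <- suppressWarnings(cor(bin[g2[1], ], bin[g2[2], ]))
    if (!is.na(cs)) sharedCor <- c(sharedCor, cs)
    if (!is.na(cr)) randomCor <- c(randomCor, cr)
  }
  expect_gt(mean(sharedCor), mean(randomCor))
})

test_that("network and labels round-trip through their text formats", {
  d <- tiny_compendium(seed = 9)
  dir <- withr::local_tempdir()
  writeNetwork(d$net, dir)
  gmt <- readGMT(file.path(dir, "tf_targets.gmt"))
  expect_identical(lapply(gmt, sort),
                   lapply(tfTargets(d$net), function(x) sort(unname(x))))
  tfs <- readTFTable(file.path(dir, "tf_gene.tsv"))
  expect_setequal(names(tfs), tfIds(d$net))
  labs <- perturbedPathways(d$se)
  f <- file.path(dir, "labels.tsv")
  writeLabelsTSV(labs, f)
  expect_identical(readLabelsTSV(f), labs)
})
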