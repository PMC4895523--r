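#' Generate a planted three-tier regulatory network
#'
#' Draws a pathway -> transcription factor -> gene hierarchy. Each pathway
#' regulates a number of TFs drawn from `tfsPerPathway`; each TF regulates a
#' number of genes drawn from `targetsPerTF`, sampled without replacement
#' within the TF (distinct TFs may share targets, exercising cooperative
#' regulation). TFs are first dealt round-robin across pathways (in random
#' order) so that, whenever the drawn pathway sizes can cover all TFs, every
#' TF belongs to at least one pathway; remaining slots are filled with TFs
#' sampled from the rest of the pool, so pathways may share TFs.
#'
#' @param config a [NetworkConfig]; `config@seed` makes the draw
#'   deterministic.
#' @return A [RegulatoryNetwork] with ids `G001...`, `TF01...`, `PW1...`.
#' @examples
#' net <- generateNetwork(networkConfig(nGenes = 100, nTFs = 10, nPathways = 3))
#' net
#' lengths(tfTargets(net))
#' @export
generateNetwork <- function(config) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  withSeed(config@seed, {
    genes <- .default_ids(config@nGenes, "G")
    tfs <- sprintf("TF%02d", seq_len(config@nTFs))
    pws <- sprintf("PW%d", seq_len(config@nPathways))

    sizes <- .sample_count_in_range(config@nPathways, config@tfsPerPathway)
    sizes <- pmin(sizes, config@nTFs)
    ## deal a random permutation of TFs round-robin to guarantee coverage
    perm <- sample(tfs)
    membership <- vector("list", config@nPathways)
    i <- 0L
    repeat {
      placed <- FALSE
      for (p in seq_len(config@nPathways)) {
        if (length(membership[[p]]) < sizes[p] && i < length(perm)) {
          i <- i + 1L
          membership[[p]] <- c(membership[[p]], perm[i])
          placed <- TRUE
        }
      }
      if (!placed || i >= length(perm)) break
    }
    for (p in seq_len(config@nPathways)) {
      need <- sizes[p] - length(membership[[p]])
      if (need > 0L) {
        pool <- setdiff(tfs, membership[[p]])
        membership[[p]] <- c(membership[[p]], sample(pool, need))
      }
    }
    pathwayTF <- data.frame(
      pathway = rep(pws, lengths(membership)),
      tf = unlist(membership, use.names = FALSE),
      stringsAsFactors = FALSE)

    nt <- .sample_count_in_range(config@nTFs, config@targetsPerTF)
    nt <- pmin(nt, config@nGenes)
    targets <- lapply(seq_len(config@nTFs), function(j) sample(genes, nt[j]))
    tfGene <- data.frame(
      tf = rep(tfs, lengths(targets)),
      gene = unlist(targets, use.names = FALSE),
      stringsAsFactors = FALSE)

    new("RegulatoryNetwork", geneIds = genes, tfIds = tfs, pathwayIds = pws,
        pathwayTF = pathwayTF, tfGene = tfGene)
  })
}

#' Simulate an experiment-vs-control perturbation compendium
#'
#' For each sample, a small number of pathways (drawn from
#' `pathwaysPerExperiment`) is perturbed; each TF of a perturbed pathway
#' activates with probability `pTFResponse`; each target of an active TF
#' becomes differentially expressed (DE) with probability `pTargetResponse`;
#' any gene is additionally DE with background probability `pBackground`.
#' DE genes receive a log2 ratio whose magnitude is Normal(`deLogratioLocation`,
#' `deLogratioSd`) (truncated at 0) with a random sign shared by all
#' responding targets of the same TF within a sample; non-DE genes receive
#' Normal(0, `nullLogratioSd`) log2 ratios.
#'
#' @param network a [RegulatoryNetwork] from [generateNetwork()].
#' @param config the matching [NetworkConfig].
#' @param nSamples number of perturbation samples to draw.
#' @param seed optional seed overriding `config@seed` (so one network can
#'   yield several independent compendia).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"logRatio"` (gene x sample log2 ratios), colData columns
#'   `perturbedPathways` and `activeTFs` (comma-joined id strings), and the
#'   network, config and planted DE-indicator matrix (`deCalls`) in
#'   `metadata()`.
#' @seealso [perturbedPathways()] to recover labels as a list.
#' @examples
#' cfg <- networkConfig(nGenes = 60, nTFs = 6, nPathways = 3, seed = 2)
#' net <- generateNetwork(cfg)
#' se <- simulateCompendium(net, cfg, nSamples = 20)
#' se
#' @export
simulateCompendium <- function(network, config, nSamples, seed = NULL) {
  stopifnot(is(network, "RegulatoryNetwork"), is(config, "NetworkConfig"))
  if (!is.numeric(nSamples) || length(nSamples) != 1L || nSamples <= 0 ||
      nSamples != floor(nSamples))
    stop("'nSamples' must be a positive integer")
  if (!all(network@geneIds == .default_ids(config@nGenes, "G")) &&
      length(network@geneIds) != config@nGenes)
    stop("network and config disagree on the gene set")
  if (is.null(seed)) seed <- config@seed
  genes <- network@geneIds
  D <- length(genes)
  targets <- tfTargets(network)
  pwTFs <- pathwayTFs(network)
  withSeed(seed, {
    vals <- matrix(0, nrow = D, ncol = nSamples,
                   dimnames = list(genes, sprintf("S%04d", seq_len(nSamples))))
    deAll <- matrix(FALSE, nrow = D, ncol = nSamples,
                    dimnames = dimnames(vals))
    pwLab <- character(nSamples)
    tfLab <- character(nSamples)
    nPW <- .sample_count_in_range(nSamples, config@pathwaysPerExperiment)
    nPW <- pmin(nPW, length(network@pathwayIds))
    for (s in seq_len(nSamples)) {
      pws <- sample(network@pathwayIds, nPW[s])
      cand <- unique(unlist(pwTFs[pws], use.names = FALSE))
      act <- cand[runif(length(cand)) < config@pTFResponse]
      de <- logical(D)
      lr <- rnorm(D, 0, config@nullLogratioSd)
      names(de) <- names(lr) <- genes
      for (tf in act) {
        tg <- targets[[tf]]
        resp <- tg[runif(length(tg)) < config@pTargetResponse]
        if (length(resp)) {
          sgn <- if (runif(1) < 0.5) -1 else 1  # shared by this TF's targets
          mag <- abs(rnorm(length(resp), config@deLogratioLocation,
                           config@deLogratioSd))
          lr[resp] <- sgn * mag
          de[resp] <- TRUE
        }
      }
      bg <- genes[runif(D) < config@pBackground]
      if (length(bg)) {
        sgn <- ifelse(runif(length(bg)) < 0.5, -1, 1)
        mag <- abs(rnorm(length(bg), config@deLogratioLocation,
                         config@deLogratioSd))
        lr[bg] <- sgn * mag
        de[bg] <- TRUE
      }
      vals[, s] <- lr
      deAll[, s] <- de
      pwLab[s] <- paste(sort(pws), collapse = ",")
      tfLab[s] <- paste(sort(act), collapse = ",")
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(logRatio = vals),
      colData = S4Vectors::DataFrame(perturbedPathways = pwLab,
                                     activeTFs = tfLab,
                                     row.names = colnames(vals)),
      metadata = list(network = network, config = config, seed = seed,
                      deCalls = deAll))
  })
}

#' Perturbation labels of a simulated compendium
#'
#' @param se a `SummarizedExperiment` from [simulateCompendium()].
#' @return Named list (one element per sample) of perturbed pathway ids.
#' @export
perturbedPathways <- function(se) {
  lab <- SummarizedExperiment::colData(se)$perturbedPathways
  if (is.null(lab)) stop("no 'perturbedPathways' column in colData")
  setNames(strsplit(as.character(lab), ",", fixed = TRUE), colnames(se))
}
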