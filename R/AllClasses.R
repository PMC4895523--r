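#' Configuration of a synthetic hierarchical regulatory network
#'
#' Bundles the parameters of the three-tier (pathway -> transcription factor
#' -> gene) generator and of the perturbation-style expression simulator.
#' Counts are numbers of entities; ranges are inclusive integer ranges given
#' as length-2 vectors; log-ratio parameters are in log2 fold-change units.
#'
#' @slot nGenes,nTFs,nPathways numbers of genes, TFs and pathways.
#' @slot targetsPerTF inclusive range of target-set sizes per TF.
#' @slot tfsPerPathway inclusive range of TF-set sizes per pathway.
#' @slot pathwaysPerExperiment inclusive range of the number of pathways
#'   perturbed in one experiment-vs-control sample.
#' @slot pTFResponse probability that a TF of a perturbed pathway activates
#'   in a given sample (1 makes TF activation deterministic).
#' @slot pTargetResponse probability that a target of an active TF becomes
#'   differentially expressed (DE) in a sample.
#' @slot pBackground per-gene per-sample background DE probability.
#' @slot deLogratioLocation mean |log2 ratio| of DE genes; must exceed
#'   log2(3) so planted DE genes clear the 3-fold call in expectation.
#' @slot deLogratioSd spread of the DE |log2 ratio| around its location.
#' @slot nullLogratioSd standard deviation of non-DE log2 ratios.
#' @slot seed integer seed making generation deterministic.
#' @export
setClass("NetworkConfig",
  representation(
    nGenes = "numeric", nTFs = "numeric", nPathways = "numeric",
    targetsPerTF = "numeric", tfsPerPathway = "numeric",
    pathwaysPerExperiment = "numeric",
    pTFResponse = "numeric", pTargetResponse = "numeric",
    pBackground = "numeric",
    deLogratioLocation = "numeric", deLogratioSd = "numeric",
    nullLogratioSd = "numeric", seed = "numeric"))

.validNetworkConfig <- function(object) {
  msg <- character()
  chkCount <- function(x, nm) {
    if (length(x) < 1L || any(!is.finite(x)) || any(x <= 0) ||
        any(x != floor(x)))
      msg <<- c(msg, sprintf("'%s' must be a positive integer", nm))
  }
  chkCount(object@nGenes, "nGenes")
  chkCount(object@nTFs, "nTFs")
  chkCount(object@nPathways, "nPathways")
  chkRange <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x)) || any(x <= 0) ||
        any(x != floor(x)) || x[1] > x[2])
      msg <<- c(msg, sprintf("'%s' must be an increasing positive integer range", nm))
  }
  chkRange(object@targetsPerTF, "targetsPerTF")
  chkRange(object@tfsPerPathway, "tfsPerPathway")
  chkRange(object@pathwaysPerExperiment, "pathwaysPerExperiment")
  chkProb <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      msg <<- c(msg, sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  chkProb(object@pTFResponse, "pTFResponse")
  chkProb(object@pTargetResponse, "pTargetResponse")
  chkProb(object@pBackground, "pBackground")
  if (length(msg) == 0L && object@nTFs > object@nGenes)
    msg <- c(msg, "'nTFs' must not exceed 'nGenes'")
  if (!is.finite(object@deLogratioLocation) ||
      object@deLogratioLocation <= log2(3))
    msg <- c(msg, "'deLogratioLocation' must exceed log2(3) so planted DE genes clear the 3-fold threshold")
  if (!is.finite(object@deLogratioSd) || object@deLogratioSd < 0)
    msg <- c(msg, "'deLogratioSd' must be >= 0")
  if (!is.finite(object@nullLogratioSd) || object@nullLogratioSd < 0)
    msg <- c(msg, "'nullLogratioSd' must be >= 0")
  if (length(msg)) msg else TRUE
}
setValidity("NetworkConfig", .validNetworkConfig)

#' @describeIn NetworkConfig Constructor with the package's study-condition
#'   defaults. Defaults emulate perturbation compendia in which each
#'   experiment engages a handful of pathways, most targets of an active TF
#'   respond, and background DE is rare.
#' @param nGenes,nTFs,nPathways,targetsPerTF,tfsPerPathway,pathwaysPerExperiment
#'   see slots.
#' @param pTFResponse,pTargetResponse,pBackground see slots.
#' @param deLogratioLocation,deLogratioSd,nullLogratioSd see slots.
#' @param seed integer seed.
#' @return A validated `NetworkConfig`.
#' @export
networkConfig <- function(nGenes = 200, nTFs = 20, nPathways = 5,
                          targetsPerTF = c(8, 15), tfsPerPathway = c(3, 5),
                          pathwaysPerExperiment = c(1, 2),
                          pTFResponse = 0.7, pTargetResponse = 0.8,
                          pBackground = 0.01,
                          deLogratioLocation = 2.0, deLogratioSd = 0.4,
                          nullLogratioSd = 0.4, seed = 1L) {
  fix2 <- function(x) if (length(x) == 1L) c(x, x) else x
  new("NetworkConfig", nGenes = nGenes, nTFs = nTFs, nPathways = nPathways,
      targetsPerTF = fix2(targetsPerTF), tfsPerPathway = fix2(tfsPerPathway),
      pathwaysPerExperiment = fix2(pathwaysPerExperiment),
      pTFResponse = pTFResponse, pTargetResponse = pTargetResponse,
      pBackground = pBackground, deLogratioLocation = deLogratioLocation,
      deLogratioSd = deLogratioSd, nullLogratioSd = nullLogratioSd,
      seed = seed)
}

#' Planted three-tier regulatory network
#'
#' Ground-truth pathway->TF and TF->gene edges used to generate synthetic
#' compendia and to score how well trained models recover the hierarchy.
#'
#' @slot geneIds,tfIds,pathwayIds identifier vectors.
#' @slot pathwayTF data.frame with columns `pathway`, `tf` (edge list).
#' @slot tfGene data.frame with columns `tf`, `gene` (edge list).
#' @export
setClass("RegulatoryNetwork",
  representation(geneIds = "character", tfIds = "character",
                 pathwayIds = "character",
                 pathwayTF = "data.frame", tfGene = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(object@tfIds)) msg <- c(msg, "duplicated TF ids")
  if (anyDuplicated(object@pathwayIds)) msg <- c(msg, "duplicated pathway ids")
  if (!all(c("pathway", "tf") %in% names(object@pathwayTF)))
    msg <- c(msg, "pathwayTF needs columns 'pathway' and 'tf'")
  if (!all(c("tf", "gene") %in% names(object@tfGene)))
    msg <- c(msg, "tfGene needs columns 'tf' and 'gene'")
  if (length(msg)) return(msg)
  if (!all(object@pathwayTF$pathway %in% object@pathwayIds))
    msg <- c(msg, "pathwayTF references unknown pathways")
  if (!all(object@pathwayTF$tf %in% object@tfIds))
    msg <- c(msg, "pathwayTF references unknown TFs")
  if (!all(object@tfGene$tf %in% object@tfIds))
    msg <- c(msg, "tfGene references unknown TFs")
  if (!all(object@tfGene$gene %in% object@geneIds))
    msg <- c(msg, "tfGene references unknown genes")
  if (anyDuplicated(object@pathwayTF)) msg <- c(msg, "duplicate pathway->TF edges")
  if (anyDuplicated(object@tfGene)) msg <- c(msg, "duplicate TF->gene edges")
  if (!all(object@tfIds %in% object@tfGene$tf))
    msg <- c(msg, "every TF must have at least one target")
  if (length(msg)) msg else TRUE
})

#' Restricted Boltzmann machine parameters
#'
#' One stage of the stacked model: a bipartite energy model over binary
#' visible units (genes or lower-layer hidden units) and binary hidden
#' units, with energy E(v,h) = -a'v - b'h - v'Wh.
#'
#' @slot W visible x hidden weight matrix.
#' @slot a visible bias vector.
#' @slot b hidden bias vector.
#' @export
setClass("RBM",
  representation(W = "matrix", a = "numeric", b = "numeric"))

setValidity("RBM", function(object) {
  msg <- character()
  if (nrow(object@W) != length(object@a))
    msg <- c(msg, "length(a) must equal nrow(W)")
  if (ncol(object@W) != length(object@b))
    msg <- c(msg, "length(b) must equal ncol(W)")
  if (!all(is.finite(object@W)) || !all(is.finite(object@a)) ||
      !all(is.finite(object@b)))
    msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Stacked sparse autoencoder model
#'
#' An ordered stack of [RBM] stages trained greedily bottom-up, optionally
#' fine-tuned by backpropagation through the unrolled encoder/decoder.
#' Layer k's hidden size equals layer k+1's visible size.
#'
#' @slot rbms list of [RBM] objects, bottom (gene-facing) first.
#' @slot architecture integer vector of hidden-layer sizes.
#' @slot finetuned logical; whether backpropagation fine-tuning was run.
#' @slot training list of training metadata (hyperparameters, seed, loss
#'   traces).
#' @export
setClass("DeepAutoencoder",
  representation(rbms = "list", architecture = "numeric",
                 finetuned = "logical", training = "list"))

setValidity("DeepAutoencoder", function(object) {
  msg <- character()
  L <- length(object@rbms)
  if (L < 1L) msg <- c(msg, "need at least one RBM")
  if (length(object@architecture) != L)
    msg <- c(msg, "architecture length must equal number of RBMs")
  for (k in seq_len(L)) {
    if (!is(object@rbms[[k]], "RBM")) {
      msg <- c(msg, "all stack elements must be RBM objects"); break
    }
    if (ncol(object@rbms[[k]]@W) != object@architecture[k])
      msg <- c(msg, sprintf("layer %d hidden size disagrees with architecture", k))
    if (k > 1L && nrow(object@rbms[[k]]@W) != ncol(object@rbms[[k - 1L]]@W))
      msg <- c(msg, sprintf("layer %d visible size must equal layer %d hidden size",
                            k, k - 1L))
  }
  if (length(msg)) msg else TRUE
})

#' Hidden-unit to transcription-factor mapping result
#'
#' Hypergeometric enrichment of each hidden unit's thresholded gene set
#' against each TF's known target set, with Benjamini-Hochberg adjustment
#' over the whole unit x TF matrix.
#'
#' @slot pvalues hidden unit x TF matrix of raw upper-tail p-values.
#' @slot adjusted matching matrix of BH-adjusted p-values.
#' @slot significant logical matrix of calls at `alpha`.
#' @slot bestHits data.frame with one row per unit: best TF (minimum
#'   adjusted p), its raw/adjusted p-values, overlap size and call.
#' @slot alpha significance level used on adjusted p-values.
#' @export
setClass("MappingResult",
  representation(pvalues = "matrix", adjusted = "matrix",
                 significant = "matrix", bestHits = "data.frame",
                 alpha = "numeric"))

setValidity("MappingResult", function(object) {
  msg <- character()
  if (any(object@pvalues < 0 | object@pvalues > 1))
    msg <- c(msg, "p-values outside [0,1]")
  if (any(object@adjusted + 1e-12 < object@pvalues))
    msg <- c(msg, "adjusted p-values must be >= raw p-values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:", object@nGenes, "genes,", object@nTFs, "TFs,",
      object@nPathways, "pathways\n")
  cat(sprintf("  targets/TF %d-%d, TFs/pathway %d-%d, pathways/experiment %d-%d\n",
              object@targetsPerTF[1], object@targetsPerTF[2],
              object@tfsPerPathway[1], object@tfsPerPathway[2],
              object@pathwaysPerExperiment[1], object@pathwaysPerExperiment[2]))
  cat(sprintf("  pTFResponse %.2f, pTargetResponse %.2f, pBackground %.3f\n",
              object@pTFResponse, object@pTargetResponse, object@pBackground))
  cat(sprintf("  DE |log2FC| ~ %.2f (sd %.2f), null sd %.2f, seed %d\n",
              object@deLogratioLocation, object@deLogratioSd,
              object@nullLogratioSd, as.integer(object@seed)))
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", length(object@pathwayIds), "pathways ->",
      length(object@tfIds), "TFs ->", length(object@geneIds), "genes\n")
  cat("  ", nrow(object@pathwayTF), " pathway->TF edges, ",
      nrow(object@tfGene), " TF->gene edges\n", sep = "")
})

setMethod("show", "RBM", function(object) {
  cat(sprintf("RBM: %d visible x %d hidden units\n",
              nrow(object@W), ncol(object@W)))
})

setMethod("show", "DeepAutoencoder", function(object) {
  cat("DeepAutoencoder:", nrow(object@rbms[[1]]@W), "visible ->",
      paste(object@architecture, collapse = " -> "), "hidden units\n")
  cat("  fine-tuned:", object@finetuned, "\n")
})

setMethod("show", "MappingResult", function(object) {
  cat(sprintf("MappingResult: %d hidden units x %d TFs (alpha = %g)\n",
              nrow(object@pvalues), ncol(object@pvalues), object@alpha))
  cat("  significant pairs:", sum(object@significant), "\n")
})

## ---- accessors -----------------------------------------------------------

#' @rdname RegulatoryNetwork-class
#' @param network a [RegulatoryNetwork].
#' @return `geneIds`, `tfIds`, `pathwayIds`: character vectors of identifiers.
#' @export
geneIds <- function(network) network@geneIds

#' @rdname RegulatoryNetwork-class
#' @export
tfIds <- function(network) network@tfIds

#' @rdname RegulatoryNetwork-class
#' @export
pathwayIds <- function(network) network@pathwayIds

#' @rdname RegulatoryNetwork-class
#' @return `tfTargets`: named list mapping each TF id to its target gene ids.
#' @export
tfTargets <- function(network) {
  split(network@tfGene$gene, factor(network@tfGene$tf, levels = network@tfIds))
}

#' @rdname RegulatoryNetwork-class
#' @return `pathwayTFs`: named list mapping each pathway id to its TF ids.
#' @export
pathwayTFs <- function(network) {
  split(network@pathwayTF$tf,
        factor(network@pathwayTF$pathway, levels = network@pathwayIds))
}

#' @rdname RBM-class
#' @param object an [RBM] or [DeepAutoencoder].
#' @param ... ignored; present for generic compatibility.
#' @return `weights`: the visible x hidden weight matrix (for a stack, a
#'   list of them); `visibleBias`/`hiddenBias`: the bias vectors.
#' @importFrom stats weights
#' @exportMethod weights
setMethod("weights", "RBM", function(object, ...) object@W)

#' @rdname DeepAutoencoder-class
#' @exportMethod weights
setMethod("weights", "DeepAutoencoder", function(object, ...)
  lapply(object@rbms, function(r) r@W))

#' @rdname RBM-class
#' @export
visibleBias <- function(object) object@a

#' @rdname RBM-class
#' @export
hiddenBias <- function(object) object@b

#' @rdname DeepAutoencoder-class
#' @param model a [DeepAutoencoder].
#' @return `architecture`: integer vector of hidden layer sizes; `nLayers`:
#'   number of hidden layers.
#' @export
architecture <- function(model) model@architecture

#' @rdname DeepAutoencoder-class
#' @export
nLayers <- function(model) length(model@rbms)

#' @rdname MappingResult-class
#' @param x a [MappingResult].
#' @return `mappingPvalues`: raw p-value matrix; `mappingAdjusted`: adjusted
#'   matrix; `bestHits`: per-unit best-TF table.
#' @export
mappingPvalues <- function(x) x@pvalues

#' @rdname MappingResult-class
#' @export
mappingAdjusted <- function(x) x@adjusted

#' @rdname MappingResult-class
#' @export
bestHits <- function(x) x@bestHits
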