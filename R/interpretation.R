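#' Effective gene-to-unit weights across layers
#'
#' Linear weight combination: the product of the stacked weight matrices
#' from the visible layer up to `layer`, giving for each hidden unit of that
#' layer an effective weight onto every gene (layer 1 returns the first
#' RBM's weights unchanged). Entry (g, u) equals the sum over all
#' gene-to-unit paths of the products of edge weights along the path.
#'
#' @param model a [DeepAutoencoder].
#' @param layer target hidden layer in `1..nLayers(model)`.
#' @return gene x unit numeric matrix.
#' @export
effectiveWeights <- function(model, layer = 1L) {
  stopifnot(is(model, "DeepAutoencoder"))
  if (layer < 1L || layer > length(model@rbms))
    stop(sprintf("'layer' must be in 1..%d", length(model@rbms)))
  W <- model@rbms[[1L]]@W
  if (layer > 1L)
    for (k in 2:layer) W <- W %*% model@rbms[[k]]@W
  colnames(W) <- sprintf("L%dU%02d", layer, seq_len(ncol(W)))
  W
}

#' Gene sets from the top fraction of absolute weights
#'
#' Retains the gene-unit edges whose |weight| lies in the top `fraction` of
#' the whole matrix (`scope = "global"`, the default reading of a top-15%
#' weight cut) or of each unit's column (`scope = "per_unit"`). Exactly
#' `ceiling(fraction * N)` edges are kept; ties at the cutoff are broken
#' deterministically by unit index then gene index.
#'
#' @param weights gene x unit matrix, e.g. from [effectiveWeights()];
#'   rownames are the gene universe.
#' @param fraction fraction of edges to keep, in (0, 1); default 0.15.
#' @param scope `"global"` or `"per_unit"`.
#' @return A list of class `"geneSetAssignment"`: `sets` (named list,
#'   unit -> gene ids), `universe`, `fraction`, `scope`.
#' @export
thresholdTopFraction <- function(weights, fraction = 0.15,
                                 scope = c("global", "per_unit")) {
  scope <- match.arg(scope)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  if (is.null(rownames(weights)))
    rownames(weights) <- .default_ids(nrow(weights), "G")
  if (is.null(colnames(weights)))
    colnames(weights) <- sprintf("U%02d", seq_len(ncol(weights)))
  keepEdge <- function(w) {
    ## w: vector of |weights| with parallel unit/gene indices already ordered
    ceiling(fraction * length(w))
  }
  sets <- vector("list", ncol(weights))
  names(sets) <- colnames(weights)
  if (scope == "global") {
    aw <- abs(weights)
    unit <- col(aw); gene <- row(aw)
    ord <- order(-aw, unit, gene)
    nKeep <- ceiling(fraction * length(aw))
    sel <- ord[seq_len(nKeep)]
    for (u in seq_len(ncol(weights))) {
      g <- gene[sel][unit[sel] == u]
      sets[[u]] <- rownames(weights)[sort(g)]
    }
  } else {
    nKeep <- ceiling(fraction * nrow(weights))
    for (u in seq_len(ncol(weights))) {
      aw <- abs(weights[, u])
      ord <- order(-aw, seq_along(aw))
      sets[[u]] <- rownames(weights)[sort(ord[seq_len(nKeep)])]
    }
  }
  structure(list(sets = sets, universe = rownames(weights),
                 fraction = fraction, scope = scope),
            class = "geneSetAssignment")
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the realized overlap `|A intersect B|`
#' when a set of size `|A|` is drawn uniformly from `universe` against a
#' fixed set of size `|B|`.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all considered ids (non-empty).
#' @return p-value `P(X >= |A intersect B|)`.
#' @examples
#' u <- letters[1:10]
#' hypergeometricOverlap(u[1:5], u[1:5], u)  # 1/choose(10, 5)
#' @export
hypergeometricOverlap <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("'universe' must be non-empty")
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of 'universe'")
  k <- length(intersect(setA, setB))
  phyper(k - 1L, length(setB), length(universe) - length(setB),
         length(setA), lower.tail = FALSE)
}

.enrichment_matrix <- function(sets, refSets, universe) {
  P <- matrix(1, nrow = length(sets), ncol = length(refSets),
              dimnames = list(names(sets), names(refSets)))
  O <- P * 0
  for (i in seq_along(sets)) {
    for (j in seq_along(refSets)) {
      P[i, j] <- hypergeometricOverlap(sets[[i]], refSets[[j]], universe)
      O[i, j] <- length(intersect(sets[[i]], refSets[[j]]))
    }
  }
  list(p = P, overlap = O)
}

#' Map hidden units to transcription factors by target enrichment
#'
#' Tests each hidden unit's gene set against each TF's known target set with
#' the upper-tail hypergeometric test over the shared gene universe,
#' Benjamini-Hochberg adjusts across the full unit x TF matrix, and reports
#' per unit the best TF (minimum adjusted p-value, ties broken by raw
#' p-value then TF order).
#'
#' @param assign a `geneSetAssignment` from [thresholdTopFraction()].
#' @param tfTargets named list: TF id -> target gene ids (e.g.
#'   [tfTargets()] of a planted network, or [readTFTable()]).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param universe gene universe; defaults to the assignment's universe
#'   (the retained genes).
#' @return A [MappingResult].
#' @export
mapUnitsToTFs <- function(assign, tfTargets, alpha = 0.05,
                          universe = assign$universe) {
  stopifnot(inherits(assign, "geneSetAssignment"))
  tfTargets <- lapply(tfTargets, intersect, universe)
  sets <- lapply(assign$sets, intersect, universe)
  em <- .enrichment_matrix(sets, tfTargets, universe)
  adj <- matrix(p.adjust(em$p, method = "BH"), nrow(em$p), ncol(em$p),
                dimnames = dimnames(em$p))
  sig <- adj <= alpha
  best <- do.call(rbind, lapply(seq_len(nrow(adj)), function(i) {
    j <- order(adj[i, ], em$p[i, ], seq_len(ncol(adj)))[1L]
    data.frame(unit = rownames(adj)[i], tf = colnames(adj)[j],
               overlap = em$overlap[i, j], p = em$p[i, j],
               adjusted = adj[i, j], significant = sig[i, j],
               stringsAsFactors = FALSE)
  }))
  new("MappingResult", pvalues = em$p, adjusted = adj, significant = sig,
      bestHits = best, alpha = alpha)
}

#' Fraction of TFs recovered as one-to-one best hits
#'
#' A TF counts as recovered one-to-one when it is the significant best hit
#' of exactly one hidden unit — the testable analogue of a close to
#' one-to-one mapping between latent variables and TFs.
#'
#' @param mapping a [MappingResult].
#' @param tfs character vector of the TFs to score (defaults to all tested).
#' @return Fraction in \[0, 1\]; the recovered TF ids are attached as
#'   `attr(, "recovered")`.
#' @export
oneToOneRecovery <- function(mapping, tfs = colnames(mapping@pvalues)) {
  hits <- bestHits(mapping)
  hits <- hits[hits$significant, , drop = FALSE]
  counts <- table(hits$tf)
  recovered <- intersect(names(counts)[counts == 1L], tfs)
  out <- length(recovered) / length(tfs)
  attr(out, "recovered") <- recovered
  out
}

#' Binary activity calls from hidden activation probabilities
#'
#' Per hidden unit, the samples whose activation probability falls in that
#' unit's top `fraction` are called active (1). Exactly
#' `ceiling(fraction * nSamples)` calls are made per unit; ties are broken
#' by sample index.
#'
#' @param states unit x sample matrix of activation probabilities, e.g. from
#'   [inferHidden()].
#' @param fraction per-unit active fraction, in (0, 1); default 0.15.
#' @return Binary unit x sample matrix.
#' @export
unitActivityCalls <- function(states, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  n <- ncol(states)
  nKeep <- ceiling(fraction * n)
  out <- matrix(0L, nrow(states), n, dimnames = dimnames(states))
  for (u in seq_len(nrow(states))) {
    ord <- order(-states[u, ], seq_len(n))
    out[u, ord[seq_len(nKeep)]] <- 1L
  }
  out
}

#' Chi-square association between unit activity and perturbation status
#'
#' Builds the 2x2 contingency table of a unit's active/inactive calls
#' against a binary perturbation indicator and performs Pearson's chi-square
#' test (no continuity correction by default) on 1 degree of freedom.
#'
#' @param unitCalls binary vector over samples (unit active or not).
#' @param perturbed binary vector over samples (condition perturbed or not).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p.value` and the 2x2 `table`.
#' @export
chisqAssociation <- function(unitCalls, perturbed, correct = FALSE) {
  if (length(unitCalls) != length(perturbed))
    stop("'unitCalls' and 'perturbed' must have equal length")
  unitCalls <- .check_state(unitCalls, length(unitCalls), "unitCalls")
  perturbed <- .check_state(perturbed, length(perturbed), "perturbed")
  tab <- matrix(c(sum(unitCalls == 1 & perturbed == 1),
                  sum(unitCalls == 1 & perturbed == 0),
                  sum(unitCalls == 0 & perturbed == 1),
                  sum(unitCalls == 0 & perturbed == 0)), 2, 2, byrow = TRUE,
                dimnames = list(unit = c("active", "inactive"),
                                condition = c("perturbed", "unperturbed")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin is zero")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value),
       table = tab)
}

#' Enrichment of unit gene sets against arbitrary annotation sets
#'
#' Generic gene-set enrichment of each unit's gene set against user-supplied
#' annotation sets (the same hypergeometric/BH machinery as
#' [mapUnitsToTFs()], for annotation collections such as process or
#' pathway gene sets).
#'
#' @inheritParams mapUnitsToTFs
#' @param annotations named list of annotation gene sets.
#' @return Long-format data.frame: unit, set, overlap, p, adjusted,
#'   significant.
#' @export
annotateGeneSets <- function(assign, annotations, alpha = 0.05,
                             universe = assign$universe) {
  res <- mapUnitsToTFs(assign, annotations, alpha, universe)
  P <- res@pvalues; A <- res@adjusted
  df <- data.frame(
    unit = rep(rownames(P), times = ncol(P)),
    set = rep(colnames(P), each = nrow(P)),
    p = as.vector(P), adjusted = as.vector(A),
    significant = as.vector(res@significant),
    stringsAsFactors = FALSE)
  df[order(df$adjusted, df$p), ]
}
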