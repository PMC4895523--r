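#' Binarize a log-ratio matrix at a fold-change threshold
#'
#' A gene is called differentially expressed (DE, entry 1) in a sample when
#' its absolute log2 ratio meets or exceeds `log2(foldThreshold)` — the
#' direction-agnostic 3-fold call used for experiment-vs-control two-colour
#' arrays. The boundary is inclusive. Missing values binarize to 0 (not DE)
#' with a message; non-finite values (Inf/NaN) are an error that names the
#' offending cells.
#'
#' @param x gene x sample numeric matrix of log2 ratios, or a
#'   `SummarizedExperiment` (assay `"logRatio"` or first assay).
#' @param foldThreshold fold-change cutoff on the natural scale (> 1);
#'   default 3.
#' @return If `x` was a `SummarizedExperiment`, the same object with a
#'   `"binary"` assay added; otherwise a 0/1 matrix with `x`'s dimnames.
#' @examples
#' m <- matrix(c(log2(3), -log2(3) - 0.01, 1), 3, 1,
#'             dimnames = list(c("g1", "g2", "g3"), "s1"))
#' binarizeExpression(m)  # 1, 1, 0
#' @export
binarizeExpression <- function(x, foldThreshold = 3) {
  if (!is.numeric(foldThreshold) || length(foldThreshold) != 1L ||
      !is.finite(foldThreshold) || foldThreshold <= 1)
    stop("'foldThreshold' must be a single number > 1")
  isSE <- is(x, "SummarizedExperiment")
  m <- if (isSE) .as_gene_matrix(x, "logRatio") else .as_gene_matrix(x)
  nas <- is.na(m) & !is.nan(m)
  if (any(nas)) {
    message(sum(nas), " missing log-ratio value(s) binarized to 0 (not DE)")
    m[nas] <- 0
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cells <- apply(head(bad, 10L), 1L, function(ij)
      sprintf("[%s, %s]",
              if (!is.null(rownames(m))) rownames(m)[ij[1]] else ij[1],
              if (!is.null(colnames(m))) colnames(m)[ij[2]] else ij[2]))
    stop("non-finite log-ratio entries at: ", paste(cells, collapse = ", "),
         if (nrow(bad) > 10L) sprintf(" (and %d more)", nrow(bad) - 10L) else "")
  }
  bin <- (abs(m) >= log2(foldThreshold)) * 1
  dimnames(bin) <- dimnames(m)
  if (isSE) {
    SummarizedExperiment::assay(x, "binary") <- bin
    x
  } else bin
}

#' Filter genes by differential-expression prevalence
#'
#' Retains exactly the genes called DE in at least `minFraction` of the
#' samples (inclusive boundary: at full scale the reference analysis keeps
#' genes changed in at least 5% of arrays). The comparison is done on DE
#' counts against `minFraction * nSamples` with a tiny guard so that exact
#' rational boundaries such as 5/100 vs 0.05 are not lost to floating-point
#' representation. Row order is preserved; columns are untouched. An empty
#' result is a warning, not an error.
#'
#' @param x binary gene x sample matrix or `SummarizedExperiment` with a
#'   `"binary"` assay.
#' @param minFraction minimum fraction of samples, in (0, 1]; default 0.05.
#' @return Same container type as `x`, restricted to the retained genes.
#' @export
filterGenes <- function(x, minFraction = 0.05) {
  if (!is.numeric(minFraction) || length(minFraction) != 1L ||
      minFraction <= 0 || minFraction > 1)
    stop("'minFraction' must be in (0, 1]")
  isSE <- is(x, "SummarizedExperiment")
  m <- if (isSE) .as_gene_matrix(x, "binary") else .as_gene_matrix(x)
  .check_binary(m, "binary expression matrix")
  keep <- rowSums(m) >= minFraction * ncol(m) - 1e-9
  if (!any(keep))
    warning("no gene passes the prevalence filter; returning an empty matrix")
  if (isSE) x[keep, ] else m[keep, , drop = FALSE]
}
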