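#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rbinom sd phyper p.adjust chisq.test kmeans
#'   hclust cutree as.dist setNames
#' @importFrom utils head read.delim write.table
NULL

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards so library calls never perturb user randomness.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Logistic function, numerically safe at large |x|.
sigmoid <- function(x) 1 / (1 + exp(-x))

## Accept a plain matrix or a SummarizedExperiment assay as gene x sample input.
.as_gene_matrix <- function(x, assay = NULL) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    if (is.null(assay)) assay <- nm[1L]
    if (!assay %in% nm)
      stop(sprintf("assay '%s' not found (available: %s)", assay,
                   paste(nm, collapse = ", ")))
    m <- SummarizedExperiment::assay(x, assay)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("expected a matrix or a SummarizedExperiment")
  }
  storage.mode(m) <- "double"
  m
}

.check_binary <- function(m, what = "matrix") {
  if (!all(m %in% c(0, 1)))
    stop(sprintf("%s must contain only 0/1 entries", what))
  invisible(m)
}

.check_unit_interval <- function(m, what = "matrix") {
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop(sprintf("%s must contain values in [0, 1]", what))
  invisible(m)
}

## Unique default ids when dimnames are absent.
.default_ids <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))

.sample_count_in_range <- function(n, range) {
  ## one draw per element from an inclusive integer range
  lo <- range[1L]; hi <- range[length(range)]
  if (lo == hi) rep.int(lo, n) else lo + floor(runif(n) * (hi - lo + 1))
}
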