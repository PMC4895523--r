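#' Read and write gene x sample matrices as TSV
#'
#' The on-disk layout is one header row of sample ids and a first column of
#' gene ids, tab-separated — the common layout of log-ratio and binary
#' expression tables.
#'
#' @param x numeric matrix with row (gene) and column (sample) names, or a
#'   `SummarizedExperiment` (first assay written).
#' @param file path.
#' @return `readMatrixTSV` returns a numeric matrix with dimnames.
#' @export
writeMatrixTSV <- function(x, file) {
  m <- .as_gene_matrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write/read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param file path.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `readGMT` returns a named list of character vectors.
#' @export
writeGMT <- function(sets, file, descriptions = NULL) {
  if (is.null(names(sets))) stop("'sets' must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeGMT
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, character(1), 1L))
}

#' Read a TF -> target table
#'
#' Accepts a two-column TSV (TF, gene; with or without a header line) or a
#' GMT file, returning the named-list form used by [mapUnitsToTFs()].
#'
#' @param file path to TSV or GMT.
#' @return Named list: TF id -> character vector of target gene ids.
#' @export
readTFTable <- function(file) {
  first <- readLines(file, n = 1L)
  if (length(strsplit(first, "\t", fixed = TRUE)[[1L]]) > 2L)
    return(readGMT(file))
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "tf")) df <- df[-1L, , drop = FALSE]
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a planted network as edge lists and GMT
#'
#' Writes `pathway_tf.tsv`, `tf_gene.tsv` (two-column edge lists with
#' headers) and `tf_targets.gmt` under `dir`.
#'
#' @param network a [RegulatoryNetwork].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeNetwork <- function(network, dir) {
  stopifnot(is(network, "RegulatoryNetwork"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "pathway_tf.tsv")
  p2 <- file.path(dir, "tf_gene.tsv")
  p3 <- file.path(dir, "tf_targets.gmt")
  write.table(network@pathwayTF, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(network@tfGene, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  writeGMT(tfTargets(network), p3)
  invisible(c(p1, p2, p3))
}

#' Write perturbation labels as two-column TSV
#'
#' @param labels named list (sample -> perturbed pathway ids), e.g. from
#'   [perturbedPathways()].
#' @param file path.
#' @return `readLabelsTSV` returns the named-list form.
#' @export
writeLabelsTSV <- function(labels, file) {
  df <- data.frame(sample_id = names(labels),
                   pathways = vapply(labels, paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeLabelsTSV
#' @export
readLabelsTSV <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  setNames(strsplit(as.character(df[[2L]]), ",", fixed = TRUE),
           as.character(df[[1L]]))
}

#' Serialize a model to a versioned JSON container
#'
#' Models are stored as plain-text JSON with a format-version field and
#' named arrays. Doubles are written as 17-significant-digit strings
#' (`%.17g`), which round-trips IEEE doubles bit-exactly; weight matrices
#' are flattened column-major next to their dimensions.
#'
#' @param model an [RBM] or [DeepAutoencoder].
#' @param file path.
#' @return `loadModel` returns the restored object.
#' @export
saveModel <- function(model, file) {
  num <- function(x) sprintf("%.17g", as.numeric(x))
  enc_rbm <- function(r) list(W = num(r@W), a = num(r@a), b = num(r@b),
                              dim = c(nrow(r@W), ncol(r@W)))
  if (is(model, "RBM")) {
    obj <- list(format = "sparseAE-model", version = 1L, type = "RBM",
                rbm = enc_rbm(model))
  } else if (is(model, "DeepAutoencoder")) {
    obj <- list(format = "sparseAE-model", version = 1L,
                type = "DeepAutoencoder",
                architecture = as.integer(model@architecture),
                finetuned = model@finetuned,
                rbms = lapply(model@rbms, enc_rbm))
  } else stop("can only serialize RBM or DeepAutoencoder objects")
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  writeLines(json, file)
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  obj <- jsonlite::fromJSON(readLines(file, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(obj$format, "sparseAE-model"))
    stop("not a sparseAE model file")
  dec_rbm <- function(r) {
    W <- matrix(as.numeric(unlist(r$W)), nrow = r$dim[1], ncol = r$dim[2])
    new("RBM", W = W, a = as.numeric(unlist(r$a)),
        b = as.numeric(unlist(r$b)))
  }
  if (identical(obj$type, "RBM")) return(dec_rbm(obj$rbm))
  rbms <- lapply(obj$rbms, dec_rbm)
  new("DeepAutoencoder", rbms = rbms,
      architecture = as.numeric(obj$architecture),
      finetuned = isTRUE(obj$finetuned), training = list())
}
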