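#' Sparse UMI count matrix with cell metadata
#'
#' Container for raw 10x-style unique molecular identifier (UMI) counts:
#' a genes x cells sparse non-negative integer matrix plus per-cell metadata
#' (sample and technical batch at minimum).
#'
#' @param counts genes x cells matrix-like of non-negative integers; coerced
#'   to a sparse `dgCMatrix`.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `counts`).
#' @param cell_ids character vector of unique cell barcodes (defaults to
#'   colnames of `counts`).
#' @param cell_meta data.frame of per-cell annotations, one row per cell.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         cell_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%05d", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stopf("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stopf("cell_ids must be unique")
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stopf("id vectors do not match matrix dimensions")
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    stopf("counts must be non-negative integers")
  if (is.null(cell_meta))
    cell_meta <- data.frame(sample = rep("sample1", ncol(counts)),
                            batch = rep("batch1", ncol(counts)))
  if (nrow(cell_meta) != ncol(counts))
    stopf("cell_meta rows (%d) != number of cells (%d)",
          nrow(cell_meta), ncol(counts))
  dimnames(counts) <- list(gene_ids, cell_ids)
  rownames(cell_meta) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Log-normalized expression matrix
#'
#' Genes x cells matrix of log-normalized expression values together with the
#' per-cell size factors and the pseudocount used, as produced by
#' [normalize_counts()].
#'
#' @param values genes x cells numeric matrix of log-normalized values.
#' @param size_factors positive per-cell size factors (mean 1 by convention).
#' @param pseudocount pseudocount added before the log.
#' @param cell_meta per-cell metadata data.frame carried along from the counts.
#' @return An object of class `NormMatrix`.
#' @export
norm_matrix <- function(values, size_factors, pseudocount = 1,
                        cell_meta = NULL) {
  values <- as.matrix(values)
  if (length(size_factors) != ncol(values))
    stopf("one size factor per cell required")
  if (any(size_factors <= 0)) stopf("size_factors must be positive")
  if (any(!is.finite(values))) stopf("normalized values must be finite")
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = colnames(values))
  structure(list(values = values, size_factors = size_factors,
                 pseudocount = pseudocount, cell_meta = cell_meta),
            class = "NormMatrix")
}

#' @export
print.NormMatrix <- function(x, ...) {
  cat(sprintf("NormMatrix: %d genes x %d cells (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' @export
dim.NormMatrix <- function(x) dim(x$values)

#' Gene-set collection
#'
#' Named list of gene-identifier vectors with an optional description per set,
#' as parsed from GMT by [read_gmt()].
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector, one per set.
#' @return An object of class `GeneSetCollection` (a named list with a
#'   `descriptions` attribute).
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("set names must be present and unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = setNames(descriptions, names(sets)),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %g\n", length(x),
              if (length(x)) median(lengths(x)) else 0))
  invisible(x)
}
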