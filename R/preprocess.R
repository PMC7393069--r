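#' Pooling-based size-factor normalization
#'
#' Per-cell size factors are estimated by deconvolving sums over overlapping
#' pools of cells (scran's pooling deconvolution), rescaled to mean 1, and
#' expression is log-transformed as `log(count / size_factor + pseudocount)`
#' (natural log). For very small inputs (< 21 cells) where pooling is not
#' meaningful, library-size factors are used instead.
#'
#' @param counts a [count_matrix()].
#' @param pseudocount pseudocount added before the log (default 1).
#' @return A [norm_matrix()].
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "CountMatrix"))
  m <- counts$counts
  if (ncol(m) < 2) stopf("normalization requires at least 2 cells")
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stopf("%d cell(s) with zero total counts", sum(tot == 0))
  if (ncol(m) >= 21) {
    sizes <- seq(21, 101, by = 20)
    sizes <- unique(pmin(sizes, ncol(m)))
    sf <- scran::calculateSumFactors(m, sizes = sizes, min.mean = 0.1)
  } else {
    sf <- tot / mean(tot)
  }
  sf <- sf / mean(sf)
  vals <- log(sweep(as.matrix(m), 2, sf, "/") + pseudocount)
  norm_matrix(vals, sf, pseudocount, counts$cell_meta)
}

#' Filter genes by detection and mean expression
#'
#' Removes genes detected (nonzero) in fewer than `min_cells` cells or with a
#' mean log-normalized value below `min_mean`.
#'
#' @param norm a [norm_matrix()].
#' @param counts the matching [count_matrix()] (detection is judged on raw
#'   counts).
#' @param min_cells minimum number of cells with a nonzero count (default 3).
#' @param min_mean minimum mean log-normalized expression (default 0.3).
#' @return list with `norm` (filtered) and `report` (a `FilterReport`).
#' @export
filter_genes <- function(norm, counts, min_cells = 3, min_mean = 0.3) {
  stopifnot(inherits(norm, "NormMatrix"), inherits(counts, "CountMatrix"))
  genes <- rownames(norm$values)
  if (!all(genes %in% counts$gene_ids)) stopf("matrices not aligned")
  nnz <- Matrix::rowSums(counts$counts[genes, , drop = FALSE] > 0)
  mean_val <- rowMeans(norm$values)
  low_cells <- nnz < min_cells
  low_mean <- !low_cells & mean_val < min_mean
  keep <- !(low_cells | low_mean)
  report <- structure(list(
    genes_removed_lowcells = sum(low_cells),
    genes_removed_lowmean = sum(low_mean),
    cells_removed_by_class = integer(0),
    thresholds = list(min_cells = min_cells, min_mean = min_mean)),
    class = "FilterReport")
  bec_log("preprocess", sprintf(
    "filter_genes: removed %d (<%d cells) + %d (mean<%g), kept %d",
    sum(low_cells), min_cells, sum(low_mean), min_mean, sum(keep)))
  out <- norm_matrix(norm$values[keep, , drop = FALSE], norm$size_factors,
                     norm$pseudocount, norm$cell_meta)
  list(norm = out, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:\n")
  cat(sprintf("  genes removed (low cells): %d\n", x$genes_removed_lowcells))
  cat(sprintf("  genes removed (low mean):  %d\n", x$genes_removed_lowmean))
  if (length(x$cells_removed_by_class))
    cat(sprintf("  cells removed [%s]: %s\n",
                paste(names(x$cells_removed_by_class), collapse = ","),
                paste(x$cells_removed_by_class, collapse = ",")))
  invisible(x)
}

#' Select highly variable genes
#'
#' Genes are ranked by the within-bin z-score of their dispersion
#' (variance / mean of log-normalized values) across `n_bins` equal-frequency
#' bins of mean expression; the top `n` are returned. Constant genes are
#' never selected; ties break lexicographically by gene id.
#'
#' @param norm a [norm_matrix()].
#' @param n number of genes to return.
#' @param n_bins number of mean-expression bins (default 20).
#' @param exclude gene ids to exclude from consideration (e.g. cell-cycle
#'   genes ahead of clustering).
#' @return character vector of gene ids, length `min(n, eligible genes)`.
#' @export
select_hvg <- function(norm, n, n_bins = 20, exclude = character(0)) {
  stopifnot(inherits(norm, "NormMatrix"))
  if (n <= 0) stopf("n must be positive")
  v <- norm$values[setdiff(rownames(norm$values), exclude), , drop = FALSE]
  mu <- rowMeans(v)
  va <- matrixStats::rowVars(v)
  eligible <- va > 0 & mu > 0
  v <- v[eligible, , drop = FALSE]
  mu <- mu[eligible]; va <- va[eligible]
  disp <- va / mu
  bins <- equal_freq_bins(mu, min(n_bins, length(mu)))
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(v))
  head(rownames(v)[ord], n)
}

#' Remove cells matching non-BEC contaminant signatures
#'
#' Scores each cell against each signature set with [module_score()] and
#' removes cells whose score for any class exceeds `threshold` (supervised
#' cell selection against lymphatic endothelium, pericytes, fibroblastic
#' reticular cells and lymphocytes).
#'
#' @param norm a [norm_matrix()].
#' @param signatures a [gene_sets()] collection, one set per contaminant
#'   class.
#' @param threshold module-score cutoff (default 0.25).
#' @param n_bins,n_ctrl,seed control-gene matching parameters passed to
#'   [module_score()].
#' @return list with `norm` (cells retained), `report` (a `FilterReport`
#'   with per-class removal counts) and `removed` (cell ids).
#' @export
remove_contaminants <- function(norm, signatures, threshold = 0.25,
                                n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(inherits(norm, "NormMatrix"))
  if (!length(signatures)) {
    return(list(norm = norm,
                report = structure(list(genes_removed_lowcells = 0L,
                                        genes_removed_lowmean = 0L,
                                        cells_removed_by_class = integer(0),
                                        thresholds = list(score = threshold)),
                                   class = "FilterReport"),
                removed = character(0)))
  }
  flagged <- matrix(FALSE, ncol(norm$values), length(signatures),
                    dimnames = list(colnames(norm$values), names(signatures)))
  for (i in seq_along(signatures)) {
    present <- intersect(signatures[[i]], rownames(norm$values))
    if (!length(present)) {
      warning(sprintf("no genes of signature '%s' present; skipped",
                      names(signatures)[i]), call. = FALSE)
      next
    }
    if (length(present) < length(signatures[[i]]))
      bec_log("preprocess", sprintf(
        "signature '%s': %d/%d genes present", names(signatures)[i],
        length(present), length(signatures[[i]])))
    sc <- module_score(norm, present, n_bins = n_bins, n_ctrl = n_ctrl,
                       seed = derive_seed(seed, names(signatures)[i]))
    flagged[, i] <- sc > threshold
  }
  drop <- rowSums(flagged) > 0
  report <- structure(list(
    genes_removed_lowcells = 0L, genes_removed_lowmean = 0L,
    cells_removed_by_class = colSums(flagged),
    thresholds = list(score = threshold)), class = "FilterReport")
  bec_log("preprocess", sprintf("removed %d contaminant cell(s)", sum(drop)))
  out <- norm_matrix(norm$values[, !drop, drop = FALSE],
                     norm$size_factors[!drop], norm$pseudocount,
                     norm$cell_meta[!drop, , drop = FALSE])
  list(norm = out, report = report,
       removed = colnames(norm$values)[drop])
}

#' Demultiplex cell sex from Y-linked genes and Xist
#'
#' Per-cell module scores for the Y-linked gene set (`sY`) and for Xist
#' (`sX`); a cell is called `M` when `sY - sX > delta`, `F` when
#' `sX - sY > delta`, otherwise `ambiguous`.
#'
#' @param norm a [norm_matrix()].
#' @param y_genes character vector of Y-linked gene ids.
#' @param xist_gene the Xist gene id.
#' @param delta decision margin (default 0.1).
#' @param n_bins,n_ctrl,seed control matching parameters for
#'   [module_score()].
#' @return data.frame with cell_id, score_y, score_x and call.
#' @export
demux_sex <- function(norm, y_genes, xist_gene, delta = 0.1,
                      n_bins = 24, n_ctrl = 100, seed = 1) {
  # control seeds derive from the gene sets themselves, so exchanging the
  # two arguments swaps the calls exactly
  seed_for <- function(genes)
    derive_seed(seed, paste(sort(genes), collapse = "|"))
  sy <- module_score(norm, y_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed_for(y_genes))
  sx <- module_score(norm, xist_gene, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed_for(xist_gene))
  call <- ifelse(sy - sx > delta, "M",
                 ifelse(sx - sy > delta, "F", "ambiguous"))
  data.frame(cell_id = colnames(norm$values), score_y = sy, score_x = sx,
             call = call, stringsAsFactors = FALSE)
}

#' Downsample every cell to a fixed read depth
#'
#' For each cell with at least `depth` total counts, exactly `depth` reads
#' are drawn without replacement (multivariate hypergeometric); cells below
#' `depth` are dropped with a logged count. Deterministic under `seed`.
#'
#' @param counts a [count_matrix()].
#' @param depth target total per cell (default 1000).
#' @param seed RNG seed.
#' @return A [count_matrix()] of the retained cells, each with total exactly
#'   `depth`.
#' @export
downsample_reads <- function(counts, depth = 1000, seed = 1) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (depth <= 0) stopf("depth must be positive")
  tot <- Matrix::colSums(counts$counts)
  keep <- which(tot >= depth)
  if (length(keep) < length(tot))
    bec_log("preprocess", sprintf(
      "downsample_reads: dropped %d cell(s) below depth %d",
      length(tot) - length(keep), depth))
  if (!length(keep)) stopf("no cell reaches depth %d", depth)
  m <- counts$counts[, keep, drop = FALSE]
  out <- with_seed_(seed, {
    res <- vector("list", ncol(m))
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      nz <- which(col > 0)
      pool <- rep.int(nz, col[nz])
      sel <- if (length(pool) == depth) pool else sample(pool, depth)
      res[[j]] <- tabulate(sel, nbins = nrow(m))
    }
    do.call(cbind, res)
  })
  dimnames(out) <- list(counts$gene_ids, counts$cell_ids[keep])
  count_matrix(out, counts$gene_ids, counts$cell_ids[keep],
               counts$cell_meta[keep, , drop = FALSE])
}
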