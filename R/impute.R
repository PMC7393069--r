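#' Build a Markov affinity graph over cells
#'
#' Adaptive-bandwidth gaussian kernel on the k-nearest-neighbour graph in a
#' low-dimensional embedding: per-cell bandwidth is the distance to the
#' `ka`-th nearest neighbour, the kernel `exp(-(d/sigma_i)^2)` is evaluated
#' over each cell's `k` nearest neighbours, symmetrized as `(K + K') / 2`,
#' and row-normalized into a transition matrix.
#'
#' @param pcs cells x d embedding matrix (typically 20 PCs of the
#'   highly-variable-gene log-normalized matrix).
#' @param k neighbours per cell (default 9).
#' @param ka adaptive-bandwidth neighbour index, `1 <= ka < k` (default 3).
#' @return An `AffinityGraph`: list with row-stochastic sparse `M`, the
#'   kernel parameters and per-cell bandwidths.
#' @export
build_markov <- function(pcs, k = 9, ka = 3) {
  pcs <- as.matrix(pcs)
  n <- nrow(pcs)
  if (k <= ka || ka < 1) stopf("require k > ka >= 1")
  if (n < k + 1) stopf("need at least k + 1 = %d cells", k + 1)
  nn <- knn_search(pcs, k)
  sigma <- nn$dist[, ka]
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  w <- exp(-(nn$dist / sigma)^2)
  K <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                            j = as.vector(nn$idx),
                            x = as.vector(w), dims = c(n, n))
  Matrix::diag(K) <- 1   # self-affinity at zero distance
  K <- (K + Matrix::t(K)) / 2
  M <- K / Matrix::rowSums(K)
  dimnames(M) <- list(rownames(pcs), rownames(pcs))
  structure(list(M = M, t = NA_integer_, k = k, ka = ka, bandwidths = sigma),
            class = "AffinityGraph")
}

#' @export
print.AffinityGraph <- function(x, ...) {
  cat(sprintf("AffinityGraph: %d cells, k = %d, ka = %d\n",
              nrow(x$M), x$k, x$ka))
  invisible(x)
}

#' Markov affinity-based imputation of expression
#'
#' Diffuses each gene's expression over the cell graph: the imputed matrix is
#' `values %*% t(M^t)`, i.e. every cell's value becomes a convex combination
#' of its graph neighbourhood after `t` diffusion steps. `t = 0` returns the
#' input exactly. Imputed values are intended for gene ordering in trajectory
#' heatmaps only, never for clustering, differential expression, scores or
#' entropy.
#'
#' @param norm a [norm_matrix()] (or plain genes x cells matrix).
#' @param graph an `AffinityGraph` from [build_markov()] over the same cells.
#' @param t integer diffusion time (default 2).
#' @return genes x cells matrix of imputed values.
#' @export
impute_expression <- function(norm, graph, t = 2) {
  vals <- if (inherits(norm, "NormMatrix")) norm$values else as.matrix(norm)
  if (t < 0 || t != round(t)) stopf("t must be a non-negative integer")
  if (ncol(vals) != nrow(graph$M))
    stopf("graph built over %d cells but matrix has %d", nrow(graph$M),
          ncol(vals))
  if (t == 0) return(vals)
  out <- t(vals)
  for (i in seq_len(t)) out <- graph$M %*% out
  # out = M^t V'; transposing back gives V (M^t)', i.e. each cell a convex
  # combination of its diffusion neighbourhood
  out <- t(as.matrix(out))
  dimnames(out) <- dimnames(vals)
  out
}
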