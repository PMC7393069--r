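#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp var median quantile sd rnorm runif rbinom rpois
#'   rnbinom rlnorm rhyper plogis pchisq pt p.adjust setNames cor dnbinom
#'   optimize aggregate rmultinom ecdf
#' @importFrom utils head tail read.table write.table
NULL

# Run `expr` under a fixed RNG state, restoring the caller's state afterwards.
# All stochastic operations in the package funnel through this so a master
# seed makes whole runs reproducible.
with_seed_ <- function(seed, expr) {
  force(seed)   # a seed drawn from the caller's RNG must advance it
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stable 31-bit integer seed derived from a master seed and a stage name, so
# per-stage randomness does not shift when other stages are toggled.
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480000
  as.integer((as.numeric(seed) %% 100000) * 20000 + h %% 20000 + 1)
}

bec_log <- function(stage, ...) {
  message(sprintf("[becatlas:%s] %s", stage, paste0(..., collapse = "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cells x n_pcs principal-component embedding of a genes x cells matrix,
# restricted to `genes`; deterministic under `seed` (truncated SVD uses a
# random start).
pca_embed <- function(values, genes = rownames(values), n_pcs = 20, seed = 1) {
  m <- t(as.matrix(values[genes, , drop = FALSE]))
  n_pcs <- min(n_pcs, ncol(m) - 1L, nrow(m) - 1L)
  pcs <- with_seed_(seed, irlba::prcomp_irlba(m, n = n_pcs, center = TRUE,
                                              scale. = FALSE))$x
  rownames(pcs) <- colnames(values)
  pcs
}

# k nearest neighbours (excluding self) among rows of `x`; returns list of
# index and distance matrices, rows aligned with `x`. With duplicated points
# the self match need not come first, so the row's own index is removed
# explicitly.
knn_search <- function(x, k) {
  k <- min(k, nrow(x) - 1L)
  res <- RANN::nn2(x, x, k = k + 1L)
  idx <- res$nn.idx; dst <- res$nn.dists
  out_i <- matrix(0L, nrow(x), k)
  out_d <- matrix(0, nrow(x), k)
  self_first <- idx[, 1] == seq_len(nrow(x))
  out_i[self_first, ] <- idx[self_first, -1, drop = FALSE]
  out_d[self_first, ] <- dst[self_first, -1, drop = FALSE]
  for (i in which(!self_first)) {
    j <- match(i, idx[i, ], nomatch = k + 1L)
    out_i[i, ] <- idx[i, -j]
    out_d[i, ] <- dst[i, -j]
  }
  list(idx = out_i, dist = out_d)
}

# Equal-frequency binning of a numeric vector into n_bins groups (used for
# expression-matched control-gene sampling and HVG dispersion z-scores).
# Average ranks keep the assignment stable under reordering of tied values.
equal_freq_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  pmin(as.integer(ceiling(r / length(x) * n_bins)), n_bins)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
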