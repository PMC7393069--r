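# Equal-frequency binning of genes by mean expression, used to draw
# expression-matched control genes.
score_bins <- function(norm, n_bins = 24) {
  mu <- rowMeans(norm$values)
  setNames(equal_freq_bins(mu, min(n_bins, length(mu))), rownames(norm$values))
}

#' Per-cell pooled gene-set score with expression-matched controls
#'
#' For each target gene, `n_ctrl` control genes are sampled with replacement
#' from its mean-expression bin; the score is the mean expression of the
#' target genes minus the mean expression of the pooled control draws, per
#' cell. Centering on bin-matched controls makes the score invariant to
#' additive shifts of the matrix and approximately zero for sets with no
#' coherent program.
#'
#' @param norm a [norm_matrix()].
#' @param target character vector of target gene ids (genes absent from the
#'   matrix are ignored; none present is an error).
#' @param n_bins number of equal-frequency expression bins (default 24).
#' @param n_ctrl control genes sampled per target gene (default 100).
#' @param seed RNG seed for control sampling.
#' @param bins optional precomputed binning from `score_bins()` so several
#'   sets can share one binning pass.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(norm, target, n_bins = 24, n_ctrl = 100, seed = 1,
                         bins = NULL) {
  stopifnot(inherits(norm, "NormMatrix"))
  target <- intersect(target, rownames(norm$values))
  if (!length(target)) stopf("no target gene present in the matrix")
  if (is.null(bins)) bins <- score_bins(norm, n_bins)
  target <- sort(target)   # gene-order invariance of control sampling
  ctrl <- with_seed_(seed, {
    unlist(lapply(target, function(g) {
      pool <- sort(names(bins)[bins == bins[[g]]])
      sample(pool, n_ctrl, replace = TRUE)
    }), use.names = FALSE)
  })
  tgt_mean <- colMeans(norm$values[target, , drop = FALSE])
  ctrl_mean <- colMeans(norm$values[ctrl, , drop = FALSE])
  tgt_mean - ctrl_mean
}

#' Score every gene set of a collection per cell
#'
#' Applies [module_score()] to each set of the collection over a single
#' shared expression binning. Sets with fewer than `min_expressed` genes
#' present in the matrix are skipped and logged. Per-set control sampling
#' seeds are derived as `seed + set index` so individual rows are
#' reproducible in isolation.
#'
#' @param norm a [norm_matrix()].
#' @param sets a [gene_sets()] collection (e.g. GO terms from [read_gmt()]).
#' @param min_expressed minimum genes present for a set to be scored
#'   (default 3).
#' @param n_bins,n_ctrl as in [module_score()].
#' @param seed master seed.
#' @return sets x cells `ScoreMatrix` (a matrix with attributes `n_bins`,
#'   `n_ctrl`, `seed` and `skipped`).
#' @export
score_all_sets <- function(norm, sets, min_expressed = 3, n_bins = 24,
                           n_ctrl = 100, seed = 1) {
  stopifnot(inherits(norm, "NormMatrix"))
  if (!length(sets)) stopf("empty gene-set collection")
  bins <- score_bins(norm, n_bins)
  present <- lapply(sets, intersect, y = rownames(norm$values))
  eligible <- lengths(present) >= min_expressed
  if (any(!eligible))
    bec_log("genescore", sprintf(
      "skipping %d set(s) with < %d expressed genes", sum(!eligible),
      min_expressed))
  idx <- which(eligible)
  rows <- lapply(idx, function(i)
    module_score(norm, present[[i]], n_ctrl = n_ctrl, seed = seed + i,
                 bins = bins))
  out <- do.call(rbind, rows)
  rownames(out) <- names(sets)[idx]
  colnames(out) <- colnames(norm$values)
  structure(out, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
            skipped = names(sets)[!eligible], class = c("ScoreMatrix",
                                                        class(out)))
}

# Vectorized one-vs-rest t-tests over the rows of a matrix.
row_t_onevsrest <- function(m, in_group, pooled = FALSE) {
  x <- m[, in_group, drop = FALSE]
  y <- m[, !in_group, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- matrixStats::rowVars(x); v2 <- matrixStats::rowVars(y)
  if (pooled) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  p[!is.finite(t)] <- 1
  data.frame(mean_diff = m1 - m2, t = t, df = df, p = p)
}

#' Differential gene-set screen across subsets
#'
#' Compares each scored set between each subset and all remaining cells
#' (one-vs-rest t-test; Welch by default, pooled-variance optionally), with
#' Benjamini-Hochberg adjustment across all (set, subset) pairs and a
#' significance flag at adjusted p below `alpha`.
#'
#' @param scores a `ScoreMatrix` from [score_all_sets()] (or any sets x cells
#'   matrix).
#' @param labels per-cell subset labels (character/factor vector aligned with
#'   the score columns, or a data.frame with a `subset` column).
#' @param alpha adjusted-p significance cutoff (default 0.001).
#' @param pooled use pooled-variance (classic Student) rather than Welch.
#' @return data.frame with set, subset, mean score difference, t, p,
#'   BH-adjusted p and significance flag.
#' @export
go_screen <- function(scores, labels, alpha = 0.001, pooled = FALSE) {
  if (is.data.frame(labels)) labels <- labels$subset
  labels <- as.character(labels)
  if (length(labels) != ncol(scores))
    stopf("one label per scored cell required")
  tab <- table(labels)
  usable <- names(tab)[tab >= 3]
  if (any(tab < 3))
    warning(sprintf("skipping subset(s) with < 3 cells: %s",
                    paste(names(tab)[tab < 3], collapse = ", ")),
            call. = FALSE)
  if (length(usable) < 2) stopf("need at least 2 subsets with >= 3 cells")
  res <- do.call(rbind, lapply(usable, function(s) {
    d <- row_t_onevsrest(scores, labels == s, pooled = pooled)
    data.frame(set = rownames(scores), subset = s, d,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res
}
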