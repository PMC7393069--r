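#' Signaling entropy rate of one expression profile over a network
#'
#' Builds the expression-weighted random walk `p_ij = A_ij x_j / sum_k A_ik
#' x_k` on the largest connected component of the interaction network,
#' finds its stationary distribution by power iteration, and returns the
#' entropy rate `SR = sum_i pi_i S_i` with local entropies
#' `S_i = -sum_j p_ij log p_ij`. The normalized rate divides by
#' `log lambda_max(A)`, the maximal entropy rate attainable on the network.
#'
#' @param expr non-negative expression vector named by gene; genes missing
#'   from the network contribute nothing, network genes missing from `expr`
#'   are treated as zero and floored.
#' @param net undirected `igraph` interaction network over gene ids.
#' @param eps expression floor guaranteeing irreducibility (default 1e-8).
#' @param tol power-iteration convergence tolerance (default 1e-10).
#' @param log_lambda_max optional precomputed `log lambda_max(A)` (reused
#'   across cells by [entropy_pipeline()]).
#' @return list with `sr`, `sr_norm`, `pi` and `local_entropy`.
#' @export
entropy_rate <- function(expr, net, eps = 1e-8, tol = 1e-10,
                         log_lambda_max = NULL) {
  comp <- igraph::components(net)
  if (comp$no == 0) stopf("empty network")
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 2) stopf("largest network component is trivial")
  net <- igraph::induced_subgraph(net, keep)
  genes <- igraph::V(net)$name
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  x <- setNames(rep(0, length(genes)), genes)
  common <- intersect(genes, names(expr))
  x[common] <- expr[common]
  core <- entropy_rate_core(x + eps, A, tol)
  if (is.null(log_lambda_max)) log_lambda_max <- log_lambda_max_of(A)
  list(sr = core$sr, sr_norm = core$sr / log_lambda_max,
       pi = setNames(core$pi, genes),
       local_entropy = setNames(core$local_entropy, genes))
}

# entropy rate of the expression-weighted walk given a (connected) adjacency
# matrix; the stationary distribution comes from power iteration on the lazy
# chain (pi P)_j = x_j (A (pi/u))_j — the half-self-loop keeps the iteration
# convergent on bipartite (periodic) graphs without changing pi
entropy_rate_core <- function(x, A, tol = 1e-10) {
  u <- as.vector(A %*% x)                 # row sums of A_ij x_j
  v <- as.vector(A %*% (x * log(x)))
  local_entropy <- log(u) - v / u
  pi_v <- x * u
  pi_v <- pi_v / sum(pi_v)                # reversible-chain guess
  for (it in seq_len(100000)) {
    nxt <- 0.5 * pi_v + 0.5 * x * as.vector(A %*% (pi_v / u))
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi_v)) < tol) { pi_v <- nxt; break }
    pi_v <- nxt
  }
  list(sr = sum(pi_v * local_entropy), pi = pi_v,
       local_entropy = local_entropy)
}

# log of the dominant eigenvalue of the (symmetric) adjacency matrix
log_lambda_max_of <- function(A, tol = 1e-12) {
  v <- rep(1 / sqrt(nrow(A)), nrow(A))
  lam <- 0
  for (it in seq_len(100000)) {
    w <- as.vector(A %*% v)
    lam_new <- sqrt(sum(w^2))
    w <- w / lam_new
    if (abs(lam_new - lam) < tol) { lam <- lam_new; break }
    lam <- lam_new; v <- w
  }
  log(lam)
}

#' Per-cell signaling entropy after fixed-depth downsampling
#'
#' Downsamples every cell to `depth` total reads (cells below depth are
#' dropped), computes the signaling entropy rate of each retained cell over
#' the network, and flags the top 1% most entropic cells.
#'
#' @param counts a [count_matrix()].
#' @param net undirected `igraph` network over gene ids overlapping the
#'   count matrix.
#' @param depth downsampling depth (default 1000).
#' @param seed RNG seed for downsampling.
#' @param top_frac top quantile to flag (default 0.01).
#' @return data.frame with cell_id, sr, sr_norm, retained and top flags.
#' @export
entropy_pipeline <- function(counts, net, depth = 1000, seed = 1,
                             top_frac = 0.01) {
  net_genes <- igraph::V(net)$name
  if (!length(intersect(net_genes, counts$gene_ids)))
    stopf("network genes do not overlap the count matrix")
  ds <- downsample_reads(counts, depth = depth, seed = seed)
  if (ncol(ds$counts) < 10) stopf("fewer than 10 cells retained")
  comp <- igraph::components(net)
  keep <- which(comp$membership == which.max(comp$csize))
  net_lcc <- igraph::induced_subgraph(net, keep)
  A <- igraph::as_adjacency_matrix(net_lcc, sparse = TRUE)
  llm <- log_lambda_max_of(A)
  genes <- igraph::V(net_lcc)$name
  m <- matrix(0, length(genes), ncol(ds$counts),
              dimnames = list(genes, ds$cell_ids))
  common <- intersect(genes, ds$gene_ids)
  m[common, ] <- as.matrix(ds$counts[common, , drop = FALSE])
  sr <- vapply(seq_len(ncol(m)), function(j) {
    entropy_rate_core(m[, j] + 1e-8, A)$sr
  }, numeric(1))
  n_top <- ceiling(top_frac * length(sr))
  top <- rank(-sr, ties.method = "first") <= n_top
  data.frame(cell_id = colnames(m), sr = sr, sr_norm = sr / llm,
             retained = TRUE, top = top, stringsAsFactors = FALSE)
}

#' Synthetic scale-free interaction network
#'
#' Barabasi-Albert preferential-attachment graph (`m` edges per new node)
#' over the supplied genes. Genes listed in `hub_genes` are mapped onto the
#' highest-degree nodes, so planted expression programs can be made to
#' occupy network hubs.
#'
#' @param gene_ids genes to place on the network.
#' @param m edges added per node (default 3).
#' @param seed RNG seed.
#' @param hub_genes genes to assign to the top-degree nodes, in order.
#' @return undirected simple `igraph` graph named by gene.
#' @export
sample_scale_free_network <- function(gene_ids, m = 3, seed = 1,
                                      hub_genes = NULL) {
  n <- length(gene_ids)
  if (n < m + 1) stopf("need more genes than m + 1")
  g <- with_seed_(seed, igraph::sample_pa(n, m = m, directed = FALSE))
  g <- igraph::simplify(g)
  deg_order <- order(-igraph::degree(g))
  nms <- character(n)
  hub_genes <- intersect(hub_genes %||% character(0), gene_ids)
  rest <- setdiff(gene_ids, hub_genes)
  nms[deg_order[seq_along(hub_genes)]] <- hub_genes
  nms[deg_order[seq_along(rest) + length(hub_genes)]] <- rest
  igraph::V(g)$name <- nms
  g
}
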