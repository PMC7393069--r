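# Shared-nearest-neighbour graph: Jaccard overlap of the (k+1)-neighbour
# lists (self included), pruned below `prune`.
snn_graph <- function(pcs, k = 20, prune = 1 / 15) {
  n <- nrow(pcs)
  nn <- knn_search(pcs, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                            j = c(as.vector(nn$idx), seq_len(n)),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)
  jac <- inter / (2 * (k + 1) - inter)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Graph clustering of the core sample
#'
#' PCA on the highly variable genes (cell-cycle genes should be excluded from
#' `hvg` beforehand), a shared-nearest-neighbour graph with Jaccard edge
#' weights, and Louvain modularity optimization at the given resolution.
#' Deterministic under `seed`.
#'
#' @param norm a [norm_matrix()].
#' @param hvg feature genes (cycle genes already excluded).
#' @param resolution modularity resolution (default 0.3).
#' @param n_pcs number of principal components (default 20).
#' @param k SNN neighbourhood size (default 20).
#' @param seed RNG seed.
#' @param pcs optional precomputed cells x d embedding (overrides PCA).
#' @return integer cluster ids named by cell.
#' @export
cluster_core <- function(norm, hvg, resolution = 0.3, n_pcs = 20, k = 20,
                         seed = 1, pcs = NULL) {
  if (is.null(pcs)) {
    stopifnot(inherits(norm, "NormMatrix"))
    if (ncol(norm$values) <= n_pcs) stopf("fewer cells than n_pcs")
    pcs <- pca_embed(norm$values, hvg, n_pcs, seed = seed)
  }
  g <- snn_graph(pcs, k = k)
  cl <- with_seed_(seed,
                   igraph::cluster_louvain(g, resolution = resolution))
  setNames(as.integer(igraph::membership(cl)), rownames(pcs))
}

#' Name major clusters by their strongest marker program
#'
#' Assigns each cluster the name of the marker set with the highest mean
#' [module_score()] over its cells; used to anchor anonymous graph-cluster
#' ids to the major BEC phenotypes.
#'
#' @param norm a [norm_matrix()].
#' @param clusters integer cluster ids from [cluster_core()].
#' @param marker_sets a [gene_sets()] collection, one set per major
#'   phenotype.
#' @param seed seed for control-gene sampling.
#' @return character vector of per-cell major labels.
#' @export
annotate_majors <- function(norm, clusters, marker_sets, seed = 1) {
  scores <- vapply(seq_along(marker_sets), function(i)
    module_score(norm, marker_sets[[i]], seed = seed + i),
    numeric(ncol(norm$values)))
  colnames(scores) <- names(marker_sets)
  by_cluster <- rowsum(scores, clusters) / as.vector(table(clusters))
  best <- colnames(scores)[max.col(by_cluster, ties.method = "first")]
  names(best) <- rownames(by_cluster)
  unname(best[as.character(clusters)])
}

#' Subdivide terminal clusters along trajectory distance
#'
#' Within the Arterial, HEC and CRP major clusters, cells beyond the
#' within-cluster quantile `q` of branch distance-from-root are relabelled
#' as the distal terminus (`Art`, `HEC-late`) or the distal origin
#' (`CRP-early`); remaining cells become `pre-Art`, `HEC` and `CRP`. Other
#' major clusters keep their names, yielding the 11-subset labelling.
#'
#' @param major_labels per-cell major phenotype labels (named by cell).
#' @param root_distance per-cell distance from the trajectory root, aligned
#'   with `major_labels`.
#' @param q quantile of within-cluster distance beyond which cells are
#'   relabelled (default 0.5); `q = 1` is the identity.
#' @return character vector of 11-subset labels.
#' @export
subdivide_termini <- function(major_labels, root_distance, q = 0.5) {
  if (length(major_labels) != length(root_distance))
    stopf("labels and distances must align")
  splits <- list(Arterial = c(near = "pre-Art", far = "Art"),
                 HEC = c(near = "HEC", far = "HEC-late"),
                 CRP = c(near = "CRP", far = "CRP-early"))
  out <- major_labels
  for (m in names(splits)) {
    idx <- which(major_labels == m)
    if (!length(idx)) stopf("major cluster '%s' absent", m)
    if (any(is.na(root_distance[idx])))
      stopf("missing trajectory distance for cluster '%s'", m)
    cut <- quantile(root_distance[idx], q)
    far <- root_distance[idx] > cut
    out[idx] <- ifelse(far, splits[[m]]["far"], splits[[m]]["near"])
  }
  out
}

#' Centroid profiles of annotated subsets
#'
#' @param norm a [norm_matrix()].
#' @param labels per-cell subset labels.
#' @param genes gene list shared by all centroids (typically ~3000 common
#'   variable genes).
#' @return genes x subsets matrix of mean log-normalized expression.
#' @export
make_centroids <- function(norm, labels, genes) {
  genes <- intersect(genes, rownames(norm$values))
  v <- norm$values[genes, , drop = FALSE]
  out <- vapply(sort(unique(labels)), function(s)
    rowMeans(v[, labels == s, drop = FALSE]), numeric(length(genes)))
  rownames(out) <- genes
  out
}

#' Transfer subset labels by maximal centroid correlation
#'
#' Each query cell is assigned the subset whose centroid profile is maximally
#' Pearson-correlated over the common gene list; ties break to the
#' lexicographically first subset (logged). The maximal correlation is
#' recorded as transfer confidence.
#'
#' @param query a [norm_matrix()].
#' @param centroids genes x subsets matrix from [make_centroids()].
#' @param min_overlap minimum common genes required (default 100).
#' @return data.frame with cell_id, subset and confidence.
#' @export
transfer_labels <- function(query, centroids, min_overlap = 100) {
  stopifnot(inherits(query, "NormMatrix"))
  if (ncol(centroids) < 2) stopf("need at least 2 centroids")
  common <- intersect(rownames(query$values), rownames(centroids))
  if (length(common) < min_overlap)
    stopf("gene overlap %d below %d", length(common), min_overlap)
  centroids <- centroids[common, sort(colnames(centroids)), drop = FALSE]
  q <- query$values[common, , drop = FALSE]
  if (any(matrixStats::colVars(q) == 0))
    stopf("zero-variance cell vector(s): %s",
          paste(head(colnames(q)[matrixStats::colVars(q) == 0]),
                collapse = ", "))
  r <- cor(q, centroids)
  best <- max.col(r, ties.method = "first")
  ties <- rowSums(r == r[cbind(seq_len(nrow(r)), best)]) > 1
  if (any(ties))
    bec_log("annotate", sprintf(
      "%d cell(s) with tied centroid correlation; lexicographic first used",
      sum(ties)))
  data.frame(cell_id = colnames(q), subset = colnames(centroids)[best],
             confidence = r[cbind(seq_len(nrow(r)), best)],
             stringsAsFactors = FALSE)
}

#' Classify cells as dividing or resting
#'
#' Pooled expression of the cell-cycle gene set via [module_score()],
#' thresholded at `tau`.
#'
#' @param norm a [norm_matrix()].
#' @param cycle_genes cell-cycle gene ids (at least 5 must be present).
#' @param tau score threshold (default 0.1).
#' @param n_bins,n_ctrl,seed control matching parameters.
#' @return logical vector named by cell; attribute `score` carries the
#'   underlying scores.
#' @export
classify_cycle <- function(norm, cycle_genes, tau = 0.1, n_bins = 24,
                           n_ctrl = 100, seed = 1) {
  present <- intersect(cycle_genes, rownames(norm$values))
  if (length(present) < 5)
    stopf("need at least 5 cycle genes present (found %d)", length(present))
  sc <- module_score(norm, present, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed)
  structure(setNames(sc > tau, colnames(norm$values)), score = sc)
}
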