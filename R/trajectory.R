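#' KNN-geodesic trajectory space
#'
#' Builds an undirected k-nearest-neighbour graph with Euclidean edge
#' weights in the embedding, raises `k` until the graph is connected
#' (logged), samples `L` seed cells uniformly without replacement, and
#' computes the cells x L matrix `T` of single-source shortest-path
#' (Dijkstra) distances from each seed. Trajectory principal components
#' (tPCs) are the PCA of `T` (centered, unscaled), first `n_tpc` retained.
#'
#' @param pcs cells x d embedding matrix with rownames.
#' @param k initial neighbourhood size (default 20).
#' @param L number of trajectory seed cells (default
#'   `min(100, ceiling(n/20))`).
#' @param seed RNG seed for seed-cell sampling.
#' @param n_tpc trajectory principal components to retain (default 5).
#' @return A `TrajectorySpace`: list with `T`, `tpc`, `seeds`, `k`, and the
#'   underlying igraph `graph`.
#' @export
tspace <- function(pcs, k = 20, L = NULL, seed = 1, n_tpc = 5) {
  pcs <- as.matrix(pcs)
  n <- nrow(pcs)
  if (is.null(rownames(pcs))) rownames(pcs) <- sprintf("cell%05d", seq_len(n))
  L <- L %||% min(100L, max(2L, ceiling(n / 20)))
  if (L > n) stopf("L (%d) exceeds number of cells (%d)", L, n)
  g <- knn_weighted_graph(pcs, k)
  while (igraph::components(g)$no > 1 && k < n - 1) {
    k <- min(n - 1, k * 2)
    bec_log("trajectory", sprintf("graph disconnected; raising k to %d", k))
    g <- knn_weighted_graph(pcs, k)
  }
  seeds <- with_seed_(seed, sort(sample.int(n, L)))
  Tm <- t(igraph::distances(g, v = seeds, algorithm = "dijkstra"))
  rownames(Tm) <- rownames(pcs)
  colnames(Tm) <- rownames(pcs)[seeds]
  n_tpc <- min(n_tpc, ncol(Tm), nrow(Tm) - 1L)
  tpc <- prcomp(Tm, center = TRUE, scale. = FALSE)$x[, seq_len(n_tpc),
                                                     drop = FALSE]
  structure(list(T = Tm, tpc = tpc, seeds = rownames(pcs)[seeds], k = k,
                 graph = g, metric = "euclidean"),
            class = "TrajectorySpace")
}

knn_weighted_graph <- function(pcs, k) {
  n <- nrow(pcs)
  nn <- knn_search(pcs, min(k, n - 1))
  from <- rep(seq_len(n), ncol(nn$idx))
  el <- cbind(from, as.vector(nn$idx))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.vector(nn$dist)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  igraph::V(g)$name <- rownames(pcs)
  g
}

#' @export
print.TrajectorySpace <- function(x, ...) {
  cat(sprintf("TrajectorySpace: %d cells x %d seeds, k = %d, %d tPCs\n",
              nrow(x$T), ncol(x$T), x$k, ncol(x$tpc)))
  invisible(x)
}

# Geodesic distance of each cell from the closest of the root cells.
root_distance <- function(traj, root_cells, cells = rownames(traj$T)) {
  d <- igraph::distances(traj$graph, v = root_cells, to = cells,
                         algorithm = "dijkstra")
  setNames(apply(d, 2, min), cells)
}

#' Isolate a trajectory branch by subset membership and tPC gates
#'
#' Selects cells belonging to the named subsets that fall inside axis-aligned
#' interval gates on the first trajectory principal components (a
#' programmatic surrogate for manual gating), and orders them by geodesic
#' distance from the root cells.
#'
#' @param traj a `TrajectorySpace`.
#' @param labels per-cell subset labels aligned with the trajectory cells.
#' @param branch_subsets subsets making up the branch, in expected order
#'   from the root.
#' @param root_cells cell ids anchoring distance zero (e.g. CRP-early cells
#'   for arterial/HEC paths, capillary cells for the venous path).
#' @param gates optional named list of `c(lo, hi)` intervals per tPC column;
#'   the default gates on the convex bounding box of the branch subsets'
#'   tPC coordinates, widened by a 5% margin.
#' @param branch_id identifier stored on the result.
#' @return A `BranchPath`: list with `branch`, ordered `cells`, `distance`
#'   from root and `scaled` distance (filled by [scale_distances()]).
#' @export
isolate_branch <- function(traj, labels, branch_subsets, root_cells,
                           gates = NULL, branch_id = NULL) {
  cells <- rownames(traj$T)
  if (length(labels) != length(cells)) stopf("labels misaligned")
  in_subset <- labels %in% branch_subsets
  if (!any(in_subset)) stopf("no cells in the requested subsets")
  if (is.null(gates)) {
    sub <- traj$tpc[in_subset, , drop = FALSE]
    gates <- lapply(seq_len(ncol(sub)), function(j) {
      r <- range(sub[, j]); m <- 0.05 * diff(r)
      c(r[1] - m, r[2] + m)
    })
    names(gates) <- colnames(traj$tpc)
  }
  inside <- rep(TRUE, length(cells))
  for (j in names(gates)) {
    if (!j %in% colnames(traj$tpc)) stopf("unknown tPC gate: %s", j)
    inside <- inside & traj$tpc[, j] >= gates[[j]][1] &
      traj$tpc[, j] <= gates[[j]][2]
  }
  keep <- in_subset & inside
  if (!any(keep)) stopf("gates exclude every cell of the branch")
  root_cells <- intersect(root_cells, cells)
  if (!length(root_cells)) stopf("no root cells present")
  d <- root_distance(traj, root_cells, cells[keep])
  ord <- order(d)
  structure(list(branch = branch_id %||% paste(branch_subsets,
                                               collapse = ">"),
                 cells = cells[keep][ord], distance = unname(d[ord]),
                 scaled = NULL, gates = gates),
            class = "BranchPath")
}

#' @export
print.BranchPath <- function(x, ...) {
  cat(sprintf("BranchPath '%s': %d cells, span %.3g%s\n", x$branch,
              length(x$cells), max(x$distance),
              if (is.null(x$scaled)) "" else " (scaled)"))
  invisible(x)
}

#' Scale branch distances to the longest path
#'
#' Divides every path's distances by the maximum distance of the longest
#' path, so the longest path ends exactly at 1 and within-path distance
#' ratios are preserved.
#'
#' @param paths list of `BranchPath` objects (a single path is allowed).
#' @return the paths with `scaled` filled in.
#' @export
scale_distances <- function(paths) {
  single <- inherits(paths, "BranchPath")
  if (single) paths <- list(paths)
  if (!length(paths)) stopf("no paths supplied")
  maxd <- max(vapply(paths, function(p) max(p$distance), numeric(1)))
  if (maxd <= 0) stopf("zero-length path")
  paths <- lapply(paths, function(p) { p$scaled <- p$distance / maxd; p })
  if (single) paths[[1]] else paths
}

#' Gaussian-kernel smoothing of expression along a trajectory
#'
#' Nadaraya-Watson estimate of per-cell values as a function of scaled
#' branch distance: `yhat(s) = sum_i w_i y_i / sum_i w_i` with
#' `w_i = exp(-(s - s_i)^2 / (2 h^2))`, evaluated on an evenly spaced grid.
#'
#' @param path a `BranchPath` with scaled distances (see
#'   [scale_distances()]).
#' @param values per-cell values: a named vector or a genes x cells matrix
#'   covering the path's cells.
#' @param h kernel bandwidth in scaled-distance units (default 0.05).
#' @param grid_n number of grid points (default 200).
#' @param grid optional explicit grid of positions.
#' @return list with `grid` and `y` (vector, or genes x grid matrix).
#' @export
smooth_along <- function(path, values, h = 0.05, grid_n = 200, grid = NULL) {
  if (!length(path$cells)) stopf("empty path")
  if (h <= 0) stopf("bandwidth must be positive")
  s <- path$scaled %||% path$distance
  if (is.null(grid)) grid <- seq(min(s), max(s), length.out = grid_n)
  w <- exp(-outer(grid, s, "-")^2 / (2 * h^2))
  w <- w / rowSums(w)
  if (is.matrix(values)) {
    y <- values[, path$cells, drop = FALSE] %*% t(w)
    list(grid = grid, y = y)
  } else {
    list(grid = grid, y = as.vector(w %*% values[path$cells]))
  }
}

#' Trajectory heatmap matrix with per-group gene ordering
#'
#' Smooths each gene along the path, fixes the gene order within each gene
#' group by average-linkage hierarchical clustering of the imputed
#' expression profiles (correlation distance), scales each row to a maximum
#' of 1 (all-zero rows are exempt and flagged), and appends pooled
#' module-score rows for any named score sets.
#'
#' @param path a scaled `BranchPath`.
#' @param gene_groups named list of gene-id vectors; genes absent from the
#'   matrix are dropped with a warning; a gene in two groups appears once
#'   per group.
#' @param imputed genes x cells imputed matrix (see [impute_expression()])
#'   used only for the clustering that fixes gene order.
#' @param norm a [norm_matrix()] supplying the values that are smoothed.
#' @param pooled_sets optional [gene_sets()] collection; each set is scored
#'   with [module_score()] and appended as an extra row.
#' @param h,grid_n smoothing parameters (see [smooth_along()]).
#' @param seed seed for pooled-score controls.
#' @return list with `matrix` (rows: ordered genes then pooled sets), `grid`,
#'   `gene_order` and `flagged` (all-zero rows).
#' @export
export_trajectory_heatmap <- function(path, gene_groups, imputed, norm,
                                      pooled_sets = NULL, h = 0.05,
                                      grid_n = 200, seed = 1) {
  rows <- list(); order_out <- character(0); grid_out <- NULL
  for (grp in names(gene_groups)) {
    genes <- gene_groups[[grp]]
    missing <- setdiff(genes, rownames(norm$values))
    if (length(missing)) {
      warning(sprintf("group '%s': dropping %d absent gene(s)", grp,
                      length(missing)), call. = FALSE)
      genes <- setdiff(genes, missing)
    }
    if (!length(genes)) next
    if (length(genes) > 2) {
      prof <- imputed[genes, , drop = FALSE]
      cc <- suppressWarnings(cor(t(prof)))
      cc[!is.finite(cc)] <- 0
      hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
      genes <- genes[hc$order]
    }
    sm <- smooth_along(path, norm$values[genes, , drop = FALSE], h = h,
                       grid_n = grid_n)
    grid_out <- sm$grid
    rn <- paste0(grp, ":", genes)
    rownames(sm$y) <- rn
    rows[[grp]] <- sm$y
    order_out <- c(order_out, rn)
  }
  mat <- do.call(rbind, rows)
  if (!is.null(pooled_sets) && length(pooled_sets)) {
    present <- vapply(pooled_sets, function(s)
      length(intersect(s, rownames(norm$values))) > 0, logical(1))
    if (any(!present)) {
      warning(sprintf("pooled set(s) with no genes present dropped: %s",
                      paste(names(pooled_sets)[!present], collapse = ", ")),
              call. = FALSE)
      pooled_sets <- pooled_sets[present]
    }
  }
  if (!is.null(pooled_sets) && length(pooled_sets)) {
    sc <- vapply(seq_along(pooled_sets), function(i)
      module_score(norm, pooled_sets[[i]], seed = seed + i),
      numeric(ncol(norm$values)))
    colnames(sc) <- names(pooled_sets)
    pooled <- smooth_along(path, t(sc), h = h, grid_n = grid_n)$y
    rownames(pooled) <- paste0("score:", names(pooled_sets))
    mat <- rbind(mat, pooled)
  }
  mx <- apply(abs(mat), 1, max)
  flagged <- rownames(mat)[mx == 0]
  scale_by <- ifelse(mx == 0, 1, mx)
  list(matrix = mat / scale_by,
       grid = grid_out %||% seq(0, 1, length.out = grid_n),
       gene_order = order_out, flagged = flagged)
}
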