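#' Detect CRP-like cells in a query dataset
#'
#' A query cell is called CRP-like when (1) its maximally correlated
#' reference centroid is CRP or CRP-early ([transfer_labels()] over the
#' common gene list against all reference subsets), and (2) after
#' mutual-nearest-neighbour alignment of the query onto the reference
#' principal-component space, at least `frac_threshold` of its `k_nn`
#' nearest reference cells are labelled CRP or CRP-early (a reproducible
#' surrogate for gating on co-embedding overlap). Both criteria are
#' required.
#'
#' @param query a [norm_matrix()] for the query tissue.
#' @param reference a [norm_matrix()] for the reference sample.
#' @param ref_labels per-cell subset labels of the reference.
#' @param feature_genes genes used for centroids and embedding (e.g. the
#'   reference variable genes); intersected with both matrices, at least
#'   100 must remain.
#' @param k_nn reference neighbours examined per query cell (default 30).
#' @param frac_threshold required CRP neighbourhood fraction (default 0.5).
#' @param n_pcs embedding dimensionality (default 20).
#' @param k_mnn MNN pairs neighbourhood (default 20).
#' @param seed RNG seed (embedding).
#' @param tissue tissue identifier recorded in the output.
#' @return `CrpCallTable` data.frame: cell_id, best_subset, r_crp,
#'   neighborhood_crp_fraction, crp_like, tissue.
#' @export
detect_crp_like <- function(query, reference, ref_labels, feature_genes,
                            k_nn = 30, frac_threshold = 0.5, n_pcs = 20,
                            k_mnn = 20, seed = 1, tissue = "query") {
  stopifnot(inherits(query, "NormMatrix"), inherits(reference, "NormMatrix"))
  common <- Reduce(intersect, list(feature_genes, rownames(query$values),
                                   rownames(reference$values)))
  if (length(common) < 100)
    stopf("only %d shared genes; need at least 100", length(common))
  crp_subsets <- c("CRP", "CRP-early")
  centroids <- make_centroids(reference, ref_labels, common)
  tr <- transfer_labels(query, centroids, min_overlap = 100)
  crit1 <- tr$subset %in% crp_subsets
  r_crp <- cor(query$values[common, , drop = FALSE],
               centroids[, "CRP", drop = FALSE])[, 1]
  # criterion 2: co-embedding neighbourhood agreement after MNN alignment
  ref_m <- t(reference$values[common, , drop = FALSE])
  ctr <- colMeans(ref_m)
  pc <- with_seed_(seed, irlba::prcomp_irlba(ref_m, n = min(n_pcs,
                                                            length(common) - 1),
                                             center = TRUE, scale. = FALSE))
  ref_pcs <- pc$x
  qry_pcs <- sweep(t(query$values[common, , drop = FALSE]), 2, ctr) %*%
    pc$rotation
  aligned <- mnn_align(list(ref_pcs, qry_pcs), k_mnn = k_mnn)
  qry_corr <- aligned$corrected[aligned$batch == 2, , drop = FALSE]
  nn <- RANN::nn2(ref_pcs, qry_corr, k = min(k_nn, nrow(ref_pcs)))$nn.idx
  ref_is_crp <- ref_labels %in% crp_subsets
  frac <- rowMeans(matrix(ref_is_crp[nn], nrow(nn)))
  data.frame(cell_id = colnames(query$values), best_subset = tr$subset,
             r_crp = r_crp, neighborhood_crp_fraction = frac,
             crp_like = crit1 & frac >= frac_threshold, tissue = tissue,
             stringsAsFactors = FALSE)
}

#' Marker-panel profile of called CRP-like cells
#'
#' Per-tissue mean expression of a CRP marker panel in called versus
#' uncalled cells. Panel genes missing from a tissue are omitted with a log
#' line; tissues with zero called cells yield an empty summary.
#'
#' @param calls a `CrpCallTable` (possibly row-bound across tissues).
#' @param query the [norm_matrix()] the calls refer to (single tissue), or a
#'   named list of matrices keyed by tissue.
#' @param panel CRP marker gene ids.
#' @return data.frame: tissue, gene, mean_called, mean_uncalled, n_called.
#' @export
crp_like_profile <- function(calls, query, panel) {
  if (inherits(query, "NormMatrix")) {
    query <- setNames(list(query), unique(calls$tissue)[1])
  }
  out <- list()
  for (t in unique(calls$tissue)) {
    ct <- calls[calls$tissue == t, ]
    qt <- query[[t]]
    if (is.null(qt)) stopf("no matrix supplied for tissue '%s'", t)
    if (!any(ct$crp_like)) next
    present <- intersect(panel, rownames(qt$values))
    if (length(present) < length(panel))
      bec_log("crp", sprintf("tissue %s: %d/%d panel genes present", t,
                             length(present), length(panel)))
    called <- ct$cell_id[ct$crp_like]
    uncalled <- ct$cell_id[!ct$crp_like]
    out[[t]] <- data.frame(
      tissue = t, gene = present,
      mean_called = rowMeans(qt$values[present, called, drop = FALSE]),
      mean_uncalled = if (length(uncalled))
        rowMeans(qt$values[present, uncalled, drop = FALSE]) else NA_real_,
      n_called = length(called), row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tissue = character(0), gene = character(0),
                      mean_called = numeric(0), mean_uncalled = numeric(0),
                      n_called = integer(0)))
  do.call(rbind, out)
}
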