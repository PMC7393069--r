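#' Mutual-nearest-neighbour batch alignment
#'
#' The first batch is the reference. For every other batch, mutual nearest
#' neighbour (MNN) cell pairs between the reference and the batch are found
#' in the shared embedding; per-pair correction vectors (reference minus
#' batch) are smoothed over the batch's cells with a gaussian kernel
#' (bandwidth a fixed multiple of the mean MNN pair distance) and added to
#' the batch coordinates. Batches are merged in list order, each onto the
#' reference.
#'
#' @param batches list of cells x d coordinate matrices sharing dimensions;
#'   the first is the reference and is returned unchanged.
#' @param k_mnn neighbours considered per direction (default 20).
#' @param bandwidth_factor kernel bandwidth as a multiple of the mean MNN
#'   pair distance (default 3).
#' @return list with `corrected` (row-bound corrected coordinates in input
#'   order), `batch` (factor of batch indices) and `corrections` (per-batch
#'   mean correction vector).
#' @export
mnn_align <- function(batches, k_mnn = 20, bandwidth_factor = 3) {
  if (length(batches) < 2) stopf("need at least 2 batches")
  d <- ncol(batches[[1]])
  if (any(vapply(batches, ncol, 1L) != d)) stopf("dimension mismatch")
  if (any(vapply(batches, nrow, 1L) < k_mnn))
    stopf("every batch needs at least k_mnn = %d cells", k_mnn)
  ref <- as.matrix(batches[[1]])
  out <- vector("list", length(batches))
  out[[1]] <- ref
  corrections <- vector("list", length(batches))
  for (b in seq_along(batches)[-1]) {
    qry <- as.matrix(batches[[b]])
    k <- min(k_mnn, nrow(ref), nrow(qry))
    fwd <- RANN::nn2(qry, ref, k = k)$nn.idx      # per ref cell: qry nbrs
    rev <- RANN::nn2(ref, qry, k = k)$nn.idx      # per qry cell: ref nbrs
    pr <- rep(seq_len(nrow(ref)), k)
    pq <- as.vector(fwd)
    mutual <- vapply(seq_along(pr), function(i)
      pr[i] %in% rev[pq[i], ], logical(1))
    if (!any(mutual)) stopf("no MNN pairs found between batch 1 and %d", b)
    pr <- pr[mutual]; pq <- pq[mutual]
    # a batch cell with an exact reference counterpart needs no correction:
    # zero-distance pairs supersede that cell's other pairs, so identical
    # batches receive an exactly null correction
    pd <- sqrt(rowSums((ref[pr, , drop = FALSE] -
                          qry[pq, , drop = FALSE])^2))
    exact_q <- unique(pq[pd < 1e-12])
    if (length(exact_q)) {
      drop_pair <- pq %in% exact_q & pd >= 1e-12
      pr <- pr[!drop_pair]; pq <- pq[!drop_pair]
    }
    vecs <- ref[pr, , drop = FALSE] - qry[pq, , drop = FALSE]
    pair_pts <- qry[pq, , drop = FALSE]
    pair_d <- sqrt(rowSums((ref[pr, , drop = FALSE] - pair_pts)^2))
    h <- bandwidth_factor * mean(pair_d)
    if (h == 0) h <- 1e-12
    # gaussian-kernel smoothing of pair vectors over the batch's cells
    d2 <- outer(rowSums(qry^2), rowSums(pair_pts^2), "+") -
      2 * qry %*% t(pair_pts)
    w <- exp(-pmax(d2, 0) / (2 * h^2))
    w <- w / pmax(rowSums(w), .Machine$double.eps)
    corr <- w %*% vecs
    out[[b]] <- qry + corr
    corrections[[b]] <- colMeans(corr)
    bec_log("mnn", sprintf(
      "batch %d: %d MNN pairs, mean |correction| = %.4g", b, length(pr),
      mean(sqrt(rowSums(corr^2)))))
  }
  list(corrected = do.call(rbind, out),
       batch = factor(rep(seq_along(batches),
                          vapply(batches, nrow, 1L))),
       corrections = corrections)
}

#' Remove the cell-cycle effect from an embedding
#'
#' Splits cells into resting and dividing, aligns the dividing cells onto
#' their resting counterparts with [mnn_align()], and substitutes the
#' corrected coordinates for the dividing cells only. Resting coordinates
#' are returned bit-identical; labels and expression are untouched (the
#' corrected embedding is for visualization and trajectory inference only).
#'
#' @param pcs cells x d embedding.
#' @param is_dividing logical vector aligned with rows of `pcs`.
#' @param k_mnn MNN neighbourhood size; if either class has fewer cells the
#'   correction is skipped with a warning.
#' @return corrected cells x d matrix in the original row order.
#' @export
remove_cycle_effect <- function(pcs, is_dividing, k_mnn = 20) {
  pcs <- as.matrix(pcs)
  if (!any(is_dividing)) return(pcs)
  if (sum(is_dividing) < k_mnn || sum(!is_dividing) < k_mnn) {
    warning(sprintf(
      "a class has fewer than k_mnn = %d cells; cycle correction skipped",
      k_mnn), call. = FALSE)
    return(pcs)
  }
  res <- mnn_align(list(pcs[!is_dividing, , drop = FALSE],
                        pcs[is_dividing, , drop = FALSE]), k_mnn = k_mnn)
  out <- pcs
  out[is_dividing, ] <- res$corrected[res$batch == 2, , drop = FALSE]
  out
}
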