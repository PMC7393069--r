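two_blob_pcs <- function(n = 150, d = 12, sep = 10, seed = 8) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d), n, d),
             sweep(matrix(rnorm(n * d), n, d), 2, c(sep, rep(0, d - 1)),
                   "+"))
  rownames(x) <- sprintf("c%03d", seq_len(2 * n))
  x
}

test_that("two separated blobs give two clusters across resolutions", {
  pcs <- two_blob_pcs()
  truth <- rep(1:2, each = 150)
  for (res in c(0.1, 0.3, 1)) {
    cl <- cluster_core(NULL, NULL, resolution = res, seed = 2, pcs = pcs)
    expect_equal(length(unique(cl)), 2)
    expect_equal(adjusted_rand(cl, truth), 1)
  }
})

test_that("the partition is invariant to cell order", {
  pcs <- two_blob_pcs(n = 120, sep = 8, seed = 9)
  cl <- cluster_core(NULL, NULL, resolution = 0.3, seed = 2, pcs = pcs)
  perm <- sample(nrow(pcs))
  cl_p <- cluster_core(NULL, NULL, resolution = 0.3, seed = 2,
                       pcs = pcs[perm, ])
  expect_equal(adjusted_rand(cl_p, cl[perm]), 1)
})

test_that("cluster naming by marker score labels planted majors", {
  f <- flow2000()
  cl <- cluster_core(f$norm, NULL, resolution = 0.3, seed = 8, pcs = f$pcs)
  major_sets <- program_gene_sets(f$programs, becatlas:::BEC_SUBSETS)
  merged <- lapply(split(seq_along(major_sets),
                         becatlas:::MAJOR_OF_SUBSET[names(major_sets)]),
                   function(i) unique(unlist(major_sets[i])))
  majors <- annotate_majors(f$norm, cl, gene_sets(merged), seed = 6)
  expect_gte(mean(majors == f$truth$major), 0.9)
})

test_that("terminus subdivision follows the distance quantile rule", {
  f <- flow2000()
  rd <- rootdist2000()
  major <- f$truth$major
  # q = 1 never relabels anything away from the parent subset
  lab_q1 <- subdivide_termini(major, rd, q = 1)
  expect_true(all(lab_q1[major == "CRP"] == "CRP"))
  expect_true(all(lab_q1[major == "HEC"] == "HEC"))
  # planted agreement at the default quantile
  lab <- subdivide_termini(major, rd, q = 0.5)
  late <- c("Art", "HEC-late", "CRP-early")
  expect_gte(mean((lab %in% late) == (f$truth$true_subset %in% late)), 0.8)
  # monotone: distal sets shrink as q grows
  n_late <- vapply(c(0.3, 0.5, 0.7, 0.9), function(q)
    sum(subdivide_termini(major, rd, q = q) %in% late), numeric(1))
  expect_true(all(diff(n_late) <= 0))
})

test_that("label transfer is exact on centroids and breaks ties low", {
  cent <- cbind(Art = c(1, 0, 0, 2), CRP = c(0, 1, 2, 0),
                Vn = c(2, 2, 0, 0))
  rownames(cent) <- paste0("g", 1:4)
  q <- norm_matrix(cent[, c("CRP", "Art"), drop = FALSE] + 0,
                   rep(1, 2))
  colnames(q$values) <- c("c1", "c2")
  tl <- transfer_labels(q, cent, min_overlap = 2)
  expect_identical(tl$subset, c("CRP", "Art"))
  expect_equal(tl$confidence, c(1, 1))
  # exact two-way tie: lexicographically first subset wins
  cent2 <- cbind(bbb = c(1, 2, 3), aaa = c(1, 2, 3))
  rownames(cent2) <- paste0("g", 1:3)
  q2 <- norm_matrix(matrix(c(1, 2, 3), 3, 1,
                           dimnames = list(paste0("g", 1:3), "c1")),
                    1)
  expect_message(tl2 <- transfer_labels(q2, cent2, min_overlap = 2), "tied")
  expect_identical(tl2$subset, "aaa")
  # zero-variance query cells are an error
  q3 <- norm_matrix(matrix(1, 3, 1, dimnames = list(paste0("g", 1:3), "c")),
                    1)
  expect_error(transfer_labels(q3, cent2, min_overlap = 2), "zero-variance")
})

test_that("transfer reproduces the core sample's own labels", {
  f <- flow2000()
  cent <- make_centroids(f$norm, f$truth$true_subset, f$hvg)
  tl <- suppressMessages(transfer_labels(f$norm, cent))
  expect_gte(mean(tl$subset == f$truth$true_subset), 0.95)
})

test_that("cycle classification is sensitive, specific and monotone in tau", {
  f <- flow2000()
  cyc <- f$programs$gene_id[f$programs$program == "cycle"]
  dv <- classify_cycle(f$norm_prefilter, cyc, seed = 5)
  tr <- f$atlas$truth[match(names(dv), f$atlas$truth$cell_id), ]
  expect_gte(mean(dv[tr$is_dividing]), 0.9)
  expect_gte(mean(!dv[!tr$is_dividing]), 0.95)
  counts_at <- vapply(c(0.05, 0.1, 0.3, 0.6), function(tau)
    sum(classify_cycle(f$norm_prefilter, cyc, tau = tau, seed = 5)),
    numeric(1))
  expect_true(all(diff(counts_at) <= 0))
  # all-zero cycle genes yield zero dividing calls
  v <- matrix(0, 6, 10, dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  v <- rbind(v, matrix(rnorm(40, 5), 4, 10,
                       dimnames = list(paste0("h", 1:4), paste0("c", 1:10))))
  expect_true(all(!classify_cycle(norm_matrix(v, rep(1, 10)),
                                  paste0("g", 1:6), seed = 1)))
  expect_error(classify_cycle(f$norm, c("nope1", "nope2")), "cycle genes")
})

test_that("identical batches need essentially no MNN correction", {
  set.seed(12)
  b <- matrix(rnorm(80 * 6), 80, 6)
  res <- suppressMessages(mnn_align(list(b, b)))
  scale <- mean(sqrt(rowSums(b^2)))
  expect_lt(sqrt(sum(res$corrections[[2]]^2)), 1e-6 * scale)
  expect_identical(res$corrected[res$batch == 1, ], b)
})

test_that("MNN recovers a planted constant batch shift", {
  set.seed(13)
  base <- matrix(rnorm(150 * 8), 150, 8)
  v <- c(4, -2, 1, 0, 0, 0, 0, 3)
  shifted <- sweep(base[76:150, ], 2, v, "+")
  res <- suppressMessages(mnn_align(list(base[1:75, ], shifted)))
  rec <- res$corrections[[2]]
  cosine <- sum(rec * (-v)) / sqrt(sum(rec^2) * sum(v^2))
  expect_gt(cosine, 0.99)
  # within-batch pairwise distances are nearly preserved (smooth correction)
  corr2 <- res$corrected[res$batch == 2, ]
  idx <- cbind(sample(75, 150, TRUE), sample(75, 150, TRUE))
  d_before <- sqrt(rowSums((shifted[idx[, 1], ] - shifted[idx[, 2], ])^2))
  d_after <- sqrt(rowSums((corr2[idx[, 1], ] - corr2[idx[, 2], ])^2))
  keep <- d_before > 1
  expect_lt(median(abs(d_after[keep] - d_before[keep]) / d_before[keep]),
            0.1)
})

test_that("cycle-effect removal fixes dividing cells, leaves resting alone", {
  f <- flow2000()
  dv <- unname(f$dividing)
  pcs_raw <- becatlas:::pca_embed(f$norm$values, f$hvg, 20, seed = 44)
  out <- suppressMessages(remove_cycle_effect(pcs_raw, dv))
  expect_identical(out[!dv, ], pcs_raw[!dv, ])
  expect_false(identical(out[dv, ], pcs_raw[dv, ]))
  # no dividing cells: identity
  expect_identical(remove_cycle_effect(pcs_raw, rep(FALSE, nrow(pcs_raw))),
                   pcs_raw)
  # tiny class: skipped with a warning
  expect_warning(remove_cycle_effect(pcs_raw[1:30, ],
                                     c(TRUE, rep(FALSE, 29))), "skipped")
  # dividing CRP cells regain CRP neighbourhoods after correction
  tr <- f$truth
  crp_div <- which(dv & tr$true_subset %in% c("CRP", "CRP-early"))
  if (length(crp_div) >= 5) {
    nn <- becatlas:::knn_search(out, 10)$idx[crp_div, , drop = FALSE]
    frac <- mean(tr$true_subset[as.vector(nn)] %in%
                   c("CRP", "CRP-early", "CapEC1"))
    expect_gte(frac, 0.7)
  }
})
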