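test_that("size factors are scale-equivariant and unit for identical cells", {
  m <- matrix(rpois(30 * 40, 5), nrow = 30)
  m_id <- m[, rep(1, 25)]                         # identical cells
  x <- count_matrix(m_id)
  nrm <- normalize_counts(x)
  expect_true(all(abs(nrm$size_factors - 1) < 1e-8))
  # doubling a cell's counts doubles its size factor relative to the source:
  # exact on the small-sample library-size path, close under deconvolution
  sm <- matrix(rpois(30 * 10, 5), nrow = 30)
  sm2 <- cbind(sm, sm[, 1] * 2)
  nsm <- normalize_counts(count_matrix(sm2))
  expect_equal(unname(nsm$size_factors[ncol(sm2)] / nsm$size_factors[1]),
               2, tolerance = 1e-9)
  big <- matrix(rpois(400 * 120, 6), nrow = 400)
  big2 <- cbind(big, big[, 1] * 2)
  nbig <- normalize_counts(count_matrix(big2))
  expect_equal(nbig$size_factors[ncol(big2)] / nbig$size_factors[1], 2,
               tolerance = 0.05)
  expect_error(normalize_counts(count_matrix(cbind(m, 0 * m[, 1]))),
               "zero total")
})

test_that("deconvolution recovers planted depth factors on the atlas", {
  cfg <- atlas_config(n_cells = 1000, seed = 13, dropout = FALSE)
  a <- generate_atlas(cfg)
  nrm <- suppressMessages(normalize_counts(a$counts))
  planted <- ifelse(a$truth$is_contaminant, cfg$contaminant_depth,
                    cfg$depth_means[a$truth$true_subset])
  expect_gt(cor(nrm$size_factors, planted), 0.99)
})

test_that("gene filtering applies the detection and mean thresholds", {
  # gene 1 nonzero in exactly 2 cells: removed; gene 2 passes both
  m <- rbind(g1 = c(5, 5, 0, 0, 0, 0),
             g2 = c(2, 2, 2, 2, 2, 2),
             g3 = c(1, 0, 1, 0, 1, 0))   # detected in 3, low mean
  x <- count_matrix(m)
  nrm <- norm_matrix(log1p(m / 2), rep(1, 6))  # mean(g3) < 0.3 scaled
  nrm$values["g3", ] <- nrm$values["g3", ] * 0.2
  fg <- suppressMessages(filter_genes(nrm, x))
  expect_false("g1" %in% rownames(fg$norm$values))
  expect_false("g3" %in% rownames(fg$norm$values))
  expect_true("g2" %in% rownames(fg$norm$values))
  expect_equal(fg$report$genes_removed_lowcells, 1)
  expect_equal(fg$report$genes_removed_lowmean, 1)
  # all-zero matrix: everything removed, totals add up
  z <- count_matrix(matrix(0L, 4, 5))
  nz <- norm_matrix(matrix(0, 4, 5, dimnames = dimnames(z$counts)),
                    rep(1, 5))
  fz <- suppressMessages(filter_genes(nz, z))
  expect_equal(nrow(fz$norm$values), 0)
  expect_equal(fz$report$genes_removed_lowcells, 4)
  # idempotence
  fg2 <- suppressMessages(filter_genes(fg$norm, x))
  expect_identical(rownames(fg2$norm$values), rownames(fg$norm$values))
})

test_that("variable-gene selection ranks planted markers above housekeeping", {
  f <- flow2000()
  markers <- f$programs$gene_id[f$programs$program %in%
                                  becatlas:::BEC_SUBSETS]
  present <- intersect(markers, rownames(f$norm$values))
  expect_gte(mean(present %in% f$hvg), 0.9)
  # constant genes are never selected
  v <- f$norm$values[1:50, ]
  v[1, ] <- 3
  nrm <- norm_matrix(v, f$norm$size_factors)
  expect_false(rownames(v)[1] %in% select_hvg(nrm, 49))
  expect_error(select_hvg(f$norm, 0), "positive")
})

test_that("hvg ties break lexicographically", {
  set.seed(1)
  base <- rpois(20, 8)
  v <- rbind(zz = base, aa = base, mm = rnorm(20, 8, 0.1))
  nrm <- norm_matrix(v, rep(1, 20))
  got <- select_hvg(nrm, 3, n_bins = 1)
  expect_lt(which(got == "aa"), which(got == "zz"))
})

test_that("contaminant removal separates planted classes from BEC", {
  f <- flow2000()
  a <- f$atlas
  nrm_all <- suppressMessages(normalize_counts(a$counts))
  rc <- suppressMessages(remove_contaminants(nrm_all,
                                             contaminant_sigs(f$programs),
                                             seed = 5))
  planted <- a$truth$cell_id[a$truth$is_contaminant]
  bec <- a$truth$cell_id[!a$truth$is_contaminant]
  expect_gte(mean(planted %in% rc$removed), 0.95)
  expect_lte(mean(bec %in% rc$removed), 0.02)
  # empty signature collection is the identity
  rc0 <- remove_contaminants(nrm_all, gene_sets(setNames(list(),
                                                         character(0))))
  expect_identical(dim(rc0$norm$values), dim(nrm_all$values))
})

test_that("sex demultiplexing recovers planted sexes and is symmetric", {
  f <- flow2000()
  y_genes <- f$programs$gene_id[f$programs$program == "Y"]
  xist <- f$programs$gene_id[f$programs$program == "Xist"]
  sx <- demux_sex(f$norm_prefilter, y_genes, xist, seed = 7)
  tr <- f$atlas$truth[match(sx$cell_id, f$atlas$truth$cell_id), ]
  called <- sx$call != "ambiguous"
  expect_gte(mean(sx$call[called] == tr$sex[called]), 0.98)
  expect_lte(mean(!called), 0.02)
  # swapping the roles of the two scores swaps the calls exactly
  swapped <- demux_sex(f$norm_prefilter, xist, y_genes, seed = 7)
  flip <- c(M = "F", F = "M", ambiguous = "ambiguous")
  expect_identical(unname(flip[sx$call]), swapped$call)
  # a cell expressing neither gene group is ambiguous
  v <- matrix(0, 8, 3, dimnames = list(paste0("g", 1:8), paste0("c", 1:3)))
  nrm <- norm_matrix(v, rep(1, 3))
  sx0 <- demux_sex(nrm, c("g1", "g2"), "g3")
  expect_true(all(sx0$call == "ambiguous"))
})

test_that("downsampling draws an exact hypergeometric subsample", {
  set.seed(2)
  m <- matrix(rpois(40 * 30, 40), 40, 30)
  m[, 1] <- 0; m[1, 1] <- 800       # a cell below depth: dropped
  x <- count_matrix(m)
  suppressMessages(ds <- downsample_reads(x, depth = 1000, seed = 9))
  expect_equal(ncol(ds$counts), 29)
  expect_true(all(Matrix::colSums(ds$counts) == 1000))
  # never exceeds the original counts
  orig <- as.matrix(x$counts[, ds$cell_ids])
  expect_true(all(as.matrix(ds$counts) <= orig))
  # deterministic under seed
  ds2 <- suppressMessages(downsample_reads(x, depth = 1000, seed = 9))
  expect_identical(as.matrix(ds$counts), as.matrix(ds2$counts))
  expect_error(downsample_reads(x, depth = 0), "positive")
})

test_that("downsampled proportions are unbiased (hypergeometric oracle)", {
  y <- c(g1 = 600L, g2 = 300L, g3 = 100L)
  x <- count_matrix(matrix(rep(y, 200), ncol = 200,
                           dimnames = list(names(y), NULL)))
  ds <- downsample_reads(x, depth = 200, seed = 11)
  avg <- rowMeans(as.matrix(ds$counts))
  expected <- 200 * y / sum(y)
  se <- sqrt(200 * (y / sum(y)) * (1 - y / sum(y)) *
               (sum(y) - 200) / (sum(y) - 1) / 200)
  expect_true(all(abs(avg - expected) < 3 * se))
})
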