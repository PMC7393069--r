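test_that("ZINB fits recover dispersion on NB data with little dropout mass", {
  set.seed(31)
  n <- 150; sf <- runif(n, 0.5, 2)
  thetas <- pi0s <- numeric(40)
  for (i in 1:40) {
    y <- rnbinom(n, mu = 5 * sf, size = 2)
    f <- zinb_fit(y, sf, rep(c("a", "b"), each = n / 2))
    thetas[i] <- f$null$theta
    pi0s[i] <- f$null$pi0
  }
  expect_lt(abs(median(thetas) - 2) / 2, 0.2)
  expect_lt(median(pi0s), 0.05)
})

test_that("the likelihood trace is non-decreasing and zeros degenerate", {
  set.seed(32)
  y <- rnbinom(80, mu = 2, size = 1)
  y[sample(80, 25)] <- 0                      # force zero inflation
  f <- zinb_fit(y, rep(1, 80), rep(c("a", "b"), each = 40))
  expect_identical(f$model, "zinb")
  expect_false(is.unsorted(f$null$trace))
  expect_false(is.unsorted(f$alt$trace))
  f0 <- zinb_fit(rep(0L, 30), rep(1, 30), rep(c("a", "b"), each = 15))
  expect_equal(f0$lrt, 0)
  expect_equal(f0$p, 1)
  expect_error(zinb_fit(1:10, rep(1, 10), rep("a", 10)), "2 groups")
  expect_error(zinb_fit(1:10, rep(1, 10), c(rep("a", 8), "b", "b")),
               "at least 3")
})

test_that("the LRT matches a grid-search profile oracle on a 20-cell toy", {
  set.seed(33)
  y <- c(rnbinom(10, mu = 8, size = 2), rnbinom(10, mu = 2, size = 2))
  sf <- rep(1, 20)
  grp <- rep(c("a", "b"), each = 10)
  theta_fix <- 2; pi0_fix <- 0.1
  f <- zinb_fit(y, sf, grp, fixed_theta = theta_fix, fixed_pi0 = pi0_fix)
  grid <- exp(seq(log(0.05), log(60), length.out = 6000))
  ll_of <- function(idx, mu) becatlas:::zinb_loglik(y[idx], mu * sf[idx],
                                                    theta_fix, pi0_fix)
  ll_null <- max(vapply(grid, function(m) ll_of(1:20, m), numeric(1)))
  ll_a <- max(vapply(grid, function(m) ll_of(1:10, m), numeric(1)))
  ll_b <- max(vapply(grid, function(m) ll_of(11:20, m), numeric(1)))
  oracle <- 2 * ((ll_a + ll_b) - ll_null)
  expect_equal(f$lrt, oracle, tolerance = 1e-3)
})

test_that("one-vs-rest DE finds planted markers and controls false calls", {
  f <- flow2000()
  tr <- f$truth
  progs <- f$programs
  set.seed(35)
  keep <- sort(sample(seq_len(nrow(tr)), 700))   # desk-scale cell subsample
  cm <- count_matrix(f$atlas$counts$counts[, tr$cell_id[keep]],
                     f$atlas$counts$gene_ids, tr$cell_id[keep])
  markers <- unlist(lapply(becatlas:::BEC_SUBSETS, function(s)
    head(progs$gene_id[progs$program == s], 8)))
  hk <- head(progs$gene_id[progs$program == "housekeeping"], 30)
  de <- suppressWarnings(de_all(cm, tr$true_subset[keep],
                                genes = c(markers, hk)))
  own <- de$subset == progs$program[match(de$gene, progs$gene_id)]
  marker_rows <- de[own & de$gene %in% markers, ]
  expect_gte(mean(marker_rows$significant & marker_rows$lfc > 0), 0.8)
  hk_rows <- de[de$gene %in% hk, ]
  expect_lte(mean(hk_rows$significant & hk_rows$lfc > 0), 0.01)
  expect_true(all(de$p_adj >= de$p - 1e-15, na.rm = TRUE))
  expect_true(all(de$lrt >= 0))
})

test_that("de_all on a single gene agrees with a standalone fit", {
  set.seed(36)
  y <- rnbinom(60, mu = c(rep(9, 30), rep(2, 30)), size = 2)
  cm <- count_matrix(matrix(y, 1, 60,
                            dimnames = list("g1", sprintf("c%02d", 1:60))))
  labels <- rep(c("in", "rest"), each = 30)
  de <- de_all(cm, labels, size_factors = rep(1, 60))
  solo <- zinb_fit(y, rep(1, 60), factor(labels, c("in", "rest")))
  row_in <- de[de$subset == "in", ]
  expect_equal(row_in$lrt, solo$lrt, tolerance = 1e-6)
  expect_equal(row_in$p, solo$p, tolerance = 1e-9)
})

test_that("signatures keep only specific, significant, upregulated genes", {
  de <- data.frame(
    gene = paste0("g", 1:6),
    subset = rep(c("A", "B"), each = 3),
    lfc = c(2, -1, 3, 1, 2, 0.5),
    specificity = c(1.5, 2, -0.2, 0.8, 0.3, 0.1),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  sig <- de_signatures(de, n = 50)
  expect_identical(sig$A, "g1")               # g2 down, g3 unspecific
  expect_identical(sig$B, c("g4", "g6"))      # ordered by specificity
  expect_identical(de_signatures(de, n = 1)$B, "g4")
  expect_length(de_signatures(de, n = 0), 0)
})

test_that("planted CRP markers enter the CRP signature and not Art's", {
  f <- flow2000()
  tr <- f$truth
  progs <- f$programs
  set.seed(37); keep <- sort(sample(seq_len(nrow(tr)), 600))
  cm <- count_matrix(f$atlas$counts$counts[, tr$cell_id[keep]],
                     f$atlas$counts$gene_ids, tr$cell_id[keep])
  crp_m <- head(progs$gene_id[progs$program == "CRP"], 6)
  art_m <- head(progs$gene_id[progs$program == "Art"], 6)
  de <- suppressWarnings(de_all(cm, tr$true_subset[keep],
                                genes = c(crp_m, art_m)))
  sig <- de_signatures(de)
  expect_gte(length(intersect(crp_m, sig$CRP)), 4)
  expect_length(intersect(crp_m, sig$Art), 0)
})

test_that("the rule of three matches the exact binomial bound", {
  expect_equal(rule_of_three_ci(0, 3)$upper, 1)
  expect_equal(rule_of_three_ci(0, 5000)$upper, 6e-4)
  expect_error(rule_of_three_ci(2, 100), "zero events")
  for (n in c(30, 50, 100, 1000, 10000)) {
    exact <- 1 - 0.05^(1 / n)
    expect_lt(abs(3 / n - exact) / exact, 0.1)
  }
})
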