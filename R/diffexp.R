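# Zero-inflated negative binomial log-likelihood. mu_cell is the per-cell
# mean (group mean times size factor); pi0 the dropout mass at zero.
zinb_loglik <- function(y, mu_cell, theta, pi0) {
  is0 <- y == 0
  ll <- numeric(length(y))
  p0 <- dnbinom(0, size = theta, mu = mu_cell[is0])
  ll[is0] <- log(pi0 + (1 - pi0) * p0 + 1e-300)
  ll[!is0] <- log(1 - pi0 + 1e-300) +
    dnbinom(y[!is0], size = theta, mu = mu_cell[!is0], log = TRUE)
  sum(ll)
}

# Coordinate-ascent maximization of the ZINB likelihood: one logistic-scale
# dropout mass and one log dispersion shared across groups, one log mean per
# group. Each 1-D step is accepted only if it improves the likelihood, so
# the trace is non-decreasing by construction.
fit_zinb_groups <- function(y, sf, group_idx, zero_inflated = TRUE,
                            maxit = 100, tol = 1e-6,
                            fixed_theta = NULL, fixed_pi0 = NULL) {
  G <- length(group_idx)
  mu0 <- vapply(group_idx, function(i)
    max(sum(y[i]) / sum(sf[i]), 1e-6), numeric(1))
  m <- mean(y / sf); v <- var(y / sf)
  theta <- min(max(m^2 / max(v - m, 1e-6), 1e-3), 1e4)
  if (!is.null(fixed_theta)) theta <- fixed_theta
  pi0 <- if (zero_inflated) 0.05 else 0
  if (!is.null(fixed_pi0)) pi0 <- fixed_pi0
  logmu <- log(mu0)
  lo_mu <- log(1e-6); hi_mu <- log(max(max(y / sf) * 10, 1))
  gmap <- integer(length(y))                # cell -> group index
  for (g in seq_len(G)) gmap[group_idx[[g]]] <- g
  ll_at <- function(logmu, theta, pi0)
    zinb_loglik(y, exp(logmu)[gmap] * sf, theta, pi0)
  ll <- ll_at(logmu, theta, pi0)
  trace <- ll
  for (it in seq_len(maxit)) {
    ll_prev <- ll
    for (g in seq_len(G)) {
      # only group g's cells depend on logmu[g]; the rest is a constant
      i <- group_idx[[g]]
      ll_g <- function(lm) zinb_loglik(y[i], exp(lm) * sf[i], theta, pi0)
      const <- ll - ll_g(logmu[g])
      opt <- optimize(ll_g,
                      c(max(lo_mu, logmu[g] - 6), min(hi_mu, logmu[g] + 6)),
                      maximum = TRUE, tol = 1e-3)
      if (const + opt$objective > ll) {
        logmu[g] <- opt$maximum; ll <- const + opt$objective
      }
    }
    if (is.null(fixed_theta)) {
      opt <- optimize(function(lt) ll_at(logmu, exp(lt), pi0),
                      c(max(log(1e-3), log(theta) - 4),
                        min(log(1e4), log(theta) + 4)),
                      maximum = TRUE, tol = 1e-3)
      if (opt$objective > ll) { theta <- exp(opt$maximum)
                               ll <- opt$objective }
    }
    if (zero_inflated && is.null(fixed_pi0)) {
      opt <- optimize(function(lp) ll_at(logmu, theta, plogis(lp)),
                      c(-12, 12), maximum = TRUE, tol = 1e-3)
      if (opt$objective > ll) { pi0 <- plogis(opt$maximum)
                               ll <- opt$objective }
    }
    trace <- c(trace, ll)
    if (ll - ll_prev < tol) break
  }
  list(mu = exp(logmu), theta = theta, pi0 = pi0, loglik = ll,
       trace = trace, converged = it < maxit || ll - ll_prev < tol,
       iterations = it)
}

# moment check: does the NB alone explain the observed zero fraction? If so
# the zero-inflation mass is dropped and a plain NB is fitted.
zinb_family <- function(y, sf) {
  mu_hat <- sum(y) / sum(sf)
  m <- mean(y / sf); v <- var(y / sf)
  theta_mom <- min(max(m^2 / max(v - m, 1e-6), 1e-3), 1e4)
  implied0 <- mean(dnbinom(0, size = theta_mom, mu = mu_hat * sf))
  mean(y == 0) > implied0 + 1e-9
}

#' Zero-inflated negative binomial likelihood-ratio test for one gene
#'
#' Fits a ZINB model with gene-wise dispersion and dropout shared across
#' groups; the null model has a single mean, the alternative one mean per
#' group. The likelihood-ratio statistic is referred to a chi-squared
#' distribution with `groups - 1` degrees of freedom. When the observed zero
#' fraction does not exceed what the negative binomial alone implies, the
#' zero-inflation mass is dropped (plain NB fit, logged via the returned
#' `model` field). Size factors enter as exposure offsets.
#'
#' @param y integer counts for one gene across cells.
#' @param size_factors positive per-cell size factors.
#' @param group factor (or coercible) with at least 2 levels, each with at
#'   least 3 cells.
#' @param maxit,tol optimizer controls.
#' @param fixed_theta,fixed_pi0 optionally pin dispersion and/or dropout
#'   (used for oracle comparisons).
#' @return list with `null`, `alt` (fits incl. likelihood traces), `lrt`,
#'   `p`, `model` ("zinb" or "nb") and `converged`.
#' @export
zinb_fit <- function(y, size_factors, group, maxit = 100, tol = 1e-6,
                     fixed_theta = NULL, fixed_pi0 = NULL) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stopf("need at least 2 groups")
  if (any(table(group) < 3)) stopf("each group needs at least 3 cells")
  if (length(y) != length(size_factors) || length(y) != length(group))
    stopf("inputs misaligned")
  if (all(y == 0))
    return(list(null = NULL, alt = NULL, lrt = 0, p = 1, model = "nb",
                converged = TRUE))
  idx <- split(seq_along(y), group)
  zi <- if (!is.null(fixed_pi0)) fixed_pi0 > 0 else zinb_family(y, size_factors)
  fit0 <- fit_zinb_groups(y, size_factors, list(seq_along(y)),
                          zero_inflated = zi, maxit = maxit, tol = tol,
                          fixed_theta = fixed_theta, fixed_pi0 = fixed_pi0)
  fit1 <- fit_zinb_groups(y, size_factors, idx, zero_inflated = zi,
                          maxit = maxit, tol = tol,
                          fixed_theta = fixed_theta, fixed_pi0 = fixed_pi0)
  lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
  converged <- fit0$converged && fit1$converged
  p <- if (converged) pchisq(lrt, df = nlevels(group) - 1,
                             lower.tail = FALSE) else NA_real_
  list(null = fit0, alt = fit1, lrt = lrt, p = p,
       model = if (zi) "zinb" else "nb", converged = converged)
}

#' One-vs-rest ZINB differential expression across subsets
#'
#' Runs [zinb_fit()] per gene per subset (subset vs all remaining cells),
#' adjusts p-values by Benjamini-Hochberg across all gene x subset tests
#' jointly, and flags significance at adjusted p below `alpha`. The
#' specificity score is the log2 ratio of the subset's normalized mean to
#' the maximum mean among all other subsets, so genes that are merely high
#' in a correlated neighbour subset score low.
#'
#' @param counts a [count_matrix()].
#' @param labels per-cell subset labels aligned with the cells.
#' @param size_factors per-cell size factors (from [normalize_counts()]);
#'   defaults to library-size factors.
#' @param genes genes to test (default: all).
#' @param alpha adjusted-p significance level (default 0.001).
#' @return `DEResult` data.frame: gene, subset, lfc, specificity, lrt, p,
#'   p_adj, significant, model, converged.
#' @export
de_all <- function(counts, labels, size_factors = NULL, genes = NULL,
                   alpha = 0.001) {
  stopifnot(inherits(counts, "CountMatrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(counts$counts)) stopf("labels misaligned")
  if (is.null(size_factors)) {
    tot <- Matrix::colSums(counts$counts)
    size_factors <- tot / mean(tot)
  }
  genes <- genes %||% counts$gene_ids
  tab <- table(labels)
  subsets <- names(tab)[tab >= 3]
  if (any(tab < 3))
    warning(sprintf("skipping degenerate subset(s): %s",
                    paste(names(tab)[tab < 3], collapse = ", ")),
            call. = FALSE)
  if (length(subsets) < 2) stopf("need at least 2 usable subsets")
  m <- as.matrix(counts$counts[genes, , drop = FALSE])
  norm_m <- sweep(m, 2, size_factors, "/")
  subset_means <- matrix(vapply(subsets, function(s)
    rowMeans(norm_m[, labels == s, drop = FALSE]), numeric(length(genes))),
    nrow = length(genes), dimnames = list(genes, subsets))
  max_other <- matrix(vapply(subsets, function(s)
    apply(subset_means[, setdiff(subsets, s), drop = FALSE], 1, max),
    numeric(length(genes))),
    nrow = length(genes), dimnames = list(genes, subsets))
  grp_idx <- lapply(subsets, function(s)
    list(which(labels == s), which(labels != s)))
  names(grp_idx) <- subsets
  rows <- vector("list", length(genes) * length(subsets))
  ri <- 0L
  for (gi in seq_along(genes)) {
    y <- m[gi, ]
    if (all(y == 0)) {
      for (s in subsets) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(gene = genes[gi], subset = s, lfc = 0,
                                 specificity = 0, lrt = 0, p = 1,
                                 model = "nb", converged = TRUE,
                                 stringsAsFactors = FALSE)
      }
      next
    }
    zi <- zinb_family(y, size_factors)
    # the null (one shared mean) does not depend on the subset split, so it
    # is fitted once per gene and reused across all one-vs-rest tests
    fit0 <- fit_zinb_groups(y, size_factors, list(seq_along(y)),
                            zero_inflated = zi)
    for (s in subsets) {
      fit1 <- fit_zinb_groups(y, size_factors, grp_idx[[s]],
                              zero_inflated = zi)
      lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
      conv <- fit0$converged && fit1$converged
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        gene = genes[gi], subset = s,
        lfc = log2((fit1$mu[1] + 1e-6) / (fit1$mu[2] + 1e-6)),
        specificity = log2((subset_means[gi, s] + 1e-6) /
                             (max_other[gi, s] + 1e-6)),
        lrt = lrt, p = if (conv) pchisq(lrt, 1, lower.tail = FALSE)
                       else NA_real_,
        model = if (zi) "zinb" else "nb", converged = conv,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows[seq_len(ri)])
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Top differentially and specifically expressed genes per subset
#'
#' Filters the DE table to significant genes with positive fold change and
#' positive specificity, and returns up to `n` genes per subset ordered by
#' specificity.
#'
#' @param de a `DEResult` from [de_all()].
#' @param n signature length cap (default 50).
#' @return named list of ordered gene vectors, one per subset.
#' @export
de_signatures <- function(de, n = 50) {
  if (n == 0) return(setNames(vector("list", 0), character(0)))
  out <- lapply(split(de, de$subset), function(d) {
    d <- d[d$significant & d$lfc > 0 & d$specificity > 0, , drop = FALSE]
    d <- d[order(-d$specificity), , drop = FALSE]
    head(d$gene, n)
  })
  out
}

#' Rule-of-three upper confidence bound for zero observed events
#'
#' With zero events in `n` independent trials, the 95% confidence interval
#' for the event probability is `[0, 3/n]`.
#'
#' @param events observed event count; must be 0 (otherwise use an exact
#'   binomial interval).
#' @param n number of trials (>= 1).
#' @return list with `lower` (0) and `upper` (3/n).
#' @export
rule_of_three_ci <- function(events = 0, n) {
  if (n < 1) stopf("n must be at least 1")
  if (events != 0)
    stopf("rule of three applies only to zero events; use an exact binomial interval (e.g. binom.test)")
  list(lower = 0, upper = min(1, 3 / n))
}
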