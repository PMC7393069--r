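# Branch layout of the planted vascular manifold. Three branches meet at a
# capillary hub (position 0): arterial (CapEC2 -> pre-Art -> Art), venous
# (TrEC -> HEC -> HEC-late, with the Vn spur leaving between TrEC and HEC),
# and crp (CapEC1 -> CRP -> CRP-early). CapIfn is an interferon-stimulated
# overlay near the arterial hub end.
# lo/hi: interval where the subset's marker program is on (parent programs
# of the three termini stay on through the terminus, so the terminus differs
# from its parent only by a weaker additional program, as in the profiled
# atlas where termini were not separable by clustering alone).
# plo/phi: interval cells of the subset occupy (defaults to lo/hi).
BRANCH_LAYOUT <- list(
  "CapEC2" = list(branch = "arterial", lo = 0.00, hi = 0.40),
  "pre-Art" = list(branch = "arterial", lo = 0.40, hi = 1.00,
                   plo = 0.40, phi = 0.70, mlo = 0.40, mhi = 1.00),
  "Art" = list(branch = "arterial", lo = 0.70, hi = 1.00, terminal = TRUE,
               plo = 0.70, phi = 1.00, mlo = 0.40, mhi = 1.00),
  "CapIfn" = list(branch = NA_character_, lo = NA, hi = NA),
  "TrEC" = list(branch = "venous", lo = 0.00, hi = 0.35),
  "HEC" = list(branch = "venous", lo = 0.35, hi = 1.00,
               plo = 0.35, phi = 0.70, mlo = 0.35, mhi = 1.00),
  "HEC-late" = list(branch = "venous", lo = 0.70, hi = 1.00, terminal = TRUE,
                    plo = 0.70, phi = 1.00, mlo = 0.35, mhi = 1.00),
  "Vn" = list(branch = "venous", lo = 0.35, hi = 0.65, spur = TRUE),
  "CapEC1" = list(branch = "crp", lo = 0.00, hi = 0.40),
  "CRP" = list(branch = "crp", lo = 0.40, hi = 1.00,
               plo = 0.40, phi = 0.75, mlo = 0.40, mhi = 1.00),
  "CRP-early" = list(branch = "crp", lo = 0.75, hi = 1.00, terminal = TRUE,
                     plo = 0.75, phi = 1.00, mlo = 0.40, mhi = 1.00))

TERMINAL_SUBSETS <- c("Art", "HEC-late", "CRP-early")

VN_JUNCTION <- 0.35   # venous position where the Vn spur leaves the main line
RAMP_W <- 0.05        # logistic ramp scale (transition ~0.2 of branch)

# Label-driven (overlay) programs, as opposed to position-driven ones.
# CapIfn is an interferon-activated capillary state without a manifold
# coordinate of its own.
OVERLAY_SUBSETS <- "CapIfn"
HUB_DECAY <- 0.30     # gaussian decay scale of the shared hub program

#' Build the planted gene-program table for a configuration
#'
#' Deterministic given the configuration seed, and independent of the cells
#' drawn, so datasets generated from configurations sharing a seed and gene
#' count (e.g. a cross-tissue panel) share the gene universe.
#'
#' @param config an [atlas_config()].
#' @return data.frame with gene_id, program, baseline and amplitude. Programs
#'   are the 11 subset markers, `cycle`, `Y`, `Xist`, `contaminant_<class>`,
#'   `go_venous`, and `housekeeping`.
#' @export
build_gene_programs <- function(config) {
  validate_atlas_config(config)
  with_seed_(derive_seed(config$seed, "genes"), {
    n <- config$n_genes
    gene_id <- sprintf("G%05d", seq_len(n))
    program <- rep("housekeeping", n)
    baseline <- rlnorm(n, meanlog = log(0.2), sdlog = 1)
    amplitude <- rep(0, n)
    i <- 1L
    take <- function(k) { idx <- i:(i + k - 1L); i <<- i + k; idx }
    # program amplitudes: termini differ from their parent cluster by a
    # weaker overlay; venous programs swing hardest (high endothelial
    # venules are the transcriptionally most distinct subsets), arterial
    # programs least, which also fixes the venous path as the longest
    # trajectory in expression space
    marker_amp <- c("Art" = 0.8, "HEC-late" = 0.8, "CRP-early" = 0.8,
                    "CapEC2" = 1.5, "pre-Art" = 1.5,
                    "TrEC" = 2.4, "HEC" = 2.4, "Vn" = 2.2,
                    "CapEC1" = 2.0, "CRP" = 2.0, "CapIfn" = 2.0)
    for (s in BEC_SUBSETS) {
      idx <- take(config$marker_program_size)
      program[idx] <- s; baseline[idx] <- 0.15
      amplitude[idx] <- marker_amp[[s]]
    }
    idx <- take(40L)
    program[idx] <- "cycle"; baseline[idx] <- 0.02; amplitude[idx] <- 1.2
    idx <- take(6L)
    program[idx] <- "Y"; baseline[idx] <- 0.005; amplitude[idx] <- 0.6
    idx <- take(1L)
    program[idx] <- "Xist"; baseline[idx] <- 0.005; amplitude[idx] <- 1.2
    for (cl in CONTAMINANT_CLASSES) {
      idx <- take(10L)
      program[idx] <- paste0("contaminant_", cl)
      baseline[idx] <- 0.01; amplitude[idx] <- 3.0
    }
    idx <- take(15L)
    program[idx] <- "go_venous"; baseline[idx] <- 0.10; amplitude[idx] <- 1.2
    idx <- take(20L)
    program[idx] <- "cap_hub"; baseline[idx] <- 0.15; amplitude[idx] <- 1.5
    data.frame(gene_id = gene_id, program = program, baseline = baseline,
               amplitude = amplitude, stringsAsFactors = FALSE)
  })
}

# smooth membership of a main-line subset at branch position u; programs of
# branch-origin subsets ramp up *from* the hub so the three branches share a
# common capillary state at position 0
ramp_intensity <- function(u, lo, hi) {
  lo_eff <- if (lo <= 0) 0.07 else lo
  hi_eff <- if (hi >= 1) 1.2 else hi
  plogis((u - lo_eff) / RAMP_W) * plogis((hi_eff - u) / RAMP_W)
}

# subsets x cells matrix of positional program intensities
position_intensities <- function(branch, pos, spur, subset) {
  branch[is.na(branch)] <- ""   # contaminants carry no branch
  pos[is.na(pos)] <- -1
  n <- length(branch)
  out <- matrix(0, length(BEC_SUBSETS), n,
                dimnames = list(BEC_SUBSETS, NULL))
  sp_prog <- pmin(pmax((pos - VN_JUNCTION) / 0.30, 0), 1)
  for (s in BEC_SUBSETS) {
    lay <- BRANCH_LAYOUT[[s]]
    if (s %in% OVERLAY_SUBSETS) {
      out[s, ] <- as.numeric(subset == s)
    } else if (isTRUE(lay$spur)) {
      on_spur <- spur & branch == lay$branch
      # broad ramp: the Vn program keeps rising along the whole spur
      out[s, on_spur] <- plogis((pos[on_spur] - 0.50) / 0.08)
    } else {
      on_main <- !spur & branch == lay$branch
      out[s, on_main] <- ramp_intensity(pos[on_main], lay$lo, lay$hi)
      # spur cells inherit the junction blend of main-line programs, fading
      # with spur progress
      if (lay$branch == "venous") {
        on_sp <- spur & branch == "venous"
        out[s, on_sp] <- ramp_intensity(VN_JUNCTION, lay$lo, lay$hi) *
          (1 - sp_prog[on_sp])
      }
    }
  }
  out
}

#' Generate a synthetic BEC atlas with planted ground truth
#'
#' Draws UMI counts per cell from a negative binomial with depth-scaled
#' program means, thinned by logistic dropout on the log mean. Cells are
#' placed continuously along three vascular branches meeting at a capillary
#' hub, with marker-program intensity a smooth logistic function of manifold
#' position so adjacent subsets blend into a phenotypic continuum. Dividing
#' cells additionally express the cell-cycle program; male cells express
#' Y-linked genes and female cells Xist; technical batches add a planted
#' per-gene log-scale shift. Reproducible under the configuration seed.
#'
#' @param config an [atlas_config()].
#' @param cell_seed optional override of the cell-level seed (the gene
#'   program table always follows `config$seed`); used by
#'   [generate_tissue_panel()].
#' @return list with `counts` ([count_matrix()]), `truth` (per-cell planted
#'   subset, branch, manifold position, division flag, sex, batch,
#'   contaminant flag) and `programs` (the gene-program table).
#' @export
generate_atlas <- function(config, cell_seed = NULL) {
  validate_atlas_config(config)
  programs <- build_gene_programs(config)
  seed <- cell_seed %||% derive_seed(config$seed, "cells")
  with_seed_(seed, {
    n <- config$n_cells
    # --- cell identities -------------------------------------------------
    cp <- config$contaminant_proportions
    classes <- c(BEC_SUBSETS, names(cp))
    probs <- c(config$subset_proportions * (1 - sum(cp)), cp)
    ident <- sample(classes, n, replace = TRUE, prob = probs)
    is_cont <- ident %in% names(cp)
    branch <- rep(NA_character_, n)
    pos <- rep(NA_real_, n)
    spur <- rep(FALSE, n)
    for (s in setdiff(BEC_SUBSETS, OVERLAY_SUBSETS)) {
      idx <- which(ident == s)
      if (!length(idx)) next
      lay <- BRANCH_LAYOUT[[s]]
      branch[idx] <- lay$branch
      # center-weighted positions: the continuum spans the full interval but
      # cell density peaks mid-subset, as in the profiled atlas where subsets
      # are modal states along a phenotypic continuum
      plo <- lay$plo %||% lay$lo; phi <- lay$phi %||% lay$hi
      mlo <- lay$mlo %||% plo; mhi <- lay$mhi %||% phi
      # positions follow one center-weighted density over the whole major
      # cluster interval, truncated to the subset's stretch, so parent and
      # terminus form a single density mode with a step (not a valley) at
      # their boundary
      qa <- stats::pbeta((plo - mlo) / (mhi - mlo), 2.5, 2.5)
      qb <- stats::pbeta((phi - mlo) / (mhi - mlo), 2.5, 2.5)
      pos[idx] <- mlo + (mhi - mlo) *
        stats::qbeta(runif(length(idx), qa, qb), 2.5, 2.5)
      spur[idx] <- isTRUE(lay$spur)
    }
    divp <- ifelse(is_cont, 0, config$division_propensity[ident])
    is_dividing <- runif(n) < divp
    sex <- ifelse(runif(n) < config$male_fraction, "M", "F")
    batch <- sample(sprintf("batch%d", seq_len(config$n_batches)), n,
                    replace = TRUE)
    sample_id <- sub("batch", "S", batch)
    cell_id <- sprintf("cell%05d", seq_len(n))

    # --- mean matrix -----------------------------------------------------
    mu <- matrix(programs$baseline, config$n_genes, n)
    pint <- position_intensities(branch, pos, spur, ident)
    pint[, is_cont] <- 0
    add_program <- function(prog, intensity) {
      rows <- which(programs$program == prog)
      if (length(rows) && any(intensity > 0))
        mu[rows, ] <<- mu[rows, ] + outer(programs$amplitude[rows], intensity)
    }
    # high endothelial venules carry marked per-cell activation
    # heterogeneity; jitter the HEC program intensities accordingly
    hec_jit <- exp(rnorm(n, 0, 0.35))
    pint["HEC", ] <- pint["HEC", ] * hec_jit
    pint["HEC-late", ] <- pint["HEC-late", ] * hec_jit
    for (s in BEC_SUBSETS) add_program(s, pint[s, ])
    add_program("cycle", as.numeric(is_dividing))
    add_program("Y", as.numeric(sex == "M"))
    add_program("Xist", as.numeric(sex == "F"))
    for (cl in names(cp))
      add_program(paste0("contaminant_", cl), as.numeric(ident == cl))
    # venous maturation program: rises along the venous branch, so the
    # venous path is the longest trajectory in expression space
    add_program("go_venous",
                ifelse(!is_cont & !is.na(branch) & branch == "venous",
                       pmax(pos, 0.1), 0.05))
    # shared capillary-hub program: high where branches meet, 0 distally;
    # the off-manifold CapIfn overlay keeps a fixed hub-proximal level
    hub_int <- ifelse(is_cont, 0,
                      ifelse(is.na(pos), 0.7, exp(-(pos / HUB_DECAY)^2)))
    add_program("cap_hub", hub_int)

    # --- depth scaling with dropout compensation -------------------------
    depth <- ifelse(is_cont, config$contaminant_depth,
                    config$depth_means[ident])
    keep_prob <- function(m)
      if (config$dropout)
        plogis(config$dropout_logit_intercept +
                 config$dropout_logit_slope * log(m))
      else 1
    mu <- sweep(mu, 2, depth / colSums(mu), "*")
    if (config$dropout) {
      for (it in 1:3) {
        kept <- colSums(mu * keep_prob(mu))
        mu <- sweep(mu, 2, depth / kept, "*")
      }
    }

    # --- batch shift -----------------------------------------------------
    if (config$n_batches > 1 && config$batch_shift_sd > 0) {
      shift <- matrix(rnorm(config$n_genes * config$n_batches, 0,
                            config$batch_shift_sd),
                      config$n_genes, config$n_batches)
      bidx <- as.integer(sub("batch", "", batch))
      mu <- mu * exp(shift[, bidx, drop = FALSE])
    }

    # --- sampling --------------------------------------------------------
    nv <- length(mu)
    counts <- if (is.infinite(config$dispersion)) rpois(nv, mu)
              else rnbinom(nv, mu = mu, size = config$dispersion)
    if (config$dropout)
      counts[runif(nv) >= keep_prob(as.vector(mu))] <- 0L
    counts <- matrix(counts, config$n_genes, n,
                     dimnames = list(programs$gene_id, cell_id))

    meta <- data.frame(sample = sample_id, batch = batch,
                       stringsAsFactors = FALSE)
    truth <- data.frame(
      cell_id = cell_id, true_subset = ident,
      major = ifelse(is_cont, NA_character_, MAJOR_OF_SUBSET[ident]),
      branch = branch, manifold_position = pos, is_spur = spur,
      is_dividing = is_dividing, sex = sex, batch = batch,
      sample = sample_id, is_contaminant = is_cont,
      stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, programs$gene_id, cell_id, meta),
         truth = truth, programs = programs)
  })
}

#' Generate a cross-tissue panel with planted CRP-like fractions
#'
#' Each tissue dataset shares the gene universe of `config` and consists of
#' capillary endothelium with the requested fraction of CRP-like cells
#' (CRP program on a capillary background), for testing cross-tissue
#' CRP detection.
#'
#' @param config an [atlas_config()]; supplies gene universe, depths and
#'   noise model.
#' @param crp_fraction_by_tissue named numeric vector of planted CRP-like
#'   fractions in `[0,1]`, one per tissue.
#' @return named list per tissue of `list(counts, truth, programs)`.
#' @export
generate_tissue_panel <- function(config, crp_fraction_by_tissue) {
  if (!length(crp_fraction_by_tissue)) stopf("empty tissue list")
  if (is.null(names(crp_fraction_by_tissue)))
    names(crp_fraction_by_tissue) <-
      sprintf("tissue%d", seq_along(crp_fraction_by_tissue))
  if (any(crp_fraction_by_tissue < 0 | crp_fraction_by_tissue > 1))
    stopf("crp fractions must be in [0,1]")
  out <- list()
  for (t in names(crp_fraction_by_tissue)) {
    f <- crp_fraction_by_tissue[[t]]
    sp <- setNames(rep(0, length(BEC_SUBSETS)), BEC_SUBSETS)
    sp["CRP"] <- 0.75 * f
    sp["CRP-early"] <- 0.25 * f
    sp["CapEC1"] <- (1 - f) / 2
    sp["CapEC2"] <- 1 - sum(sp[c("CRP", "CRP-early", "CapEC1")])
    cfg_t <- config
    cfg_t$subset_proportions <- sp
    cfg_t$contaminant_proportions <-
      setNames(numeric(0), character(0))
    validate_atlas_config(cfg_t)
    out[[t]] <- generate_atlas(cfg_t,
                               cell_seed = derive_seed(config$seed,
                                                       paste0("tissue_", t)))
  }
  out
}

#' Write an atlas to disk as MatrixMarket triplet plus truth tables
#'
#' @param atlas result of [generate_atlas()].
#' @param dir output directory.
#' @param gzip gzip the matrix triplet.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir, gzip = FALSE) {
  write_counts(atlas$counts, dir, gzip = gzip)
  write.table(atlas$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(atlas$programs, file.path(dir, "gene_programs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
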