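BEC_SUBSETS <- c("Art", "pre-Art", "HEC", "HEC-late", "Vn", "CapEC1",
                 "CapEC2", "CapIfn", "TrEC", "CRP", "CRP-early")
CONTAMINANT_CLASSES <- c("LEC", "pericyte", "FRC", "lymphocyte")

# Major phenotypes: the 11 subsets collapse to 8 by merging the arterial,
# HEC and CRP termini with their parent clusters.
MAJOR_OF_SUBSET <- c("Art" = "Arterial", "pre-Art" = "Arterial",
                     "HEC" = "HEC", "HEC-late" = "HEC", "Vn" = "Vn",
                     "CapEC1" = "CapEC1", "CapEC2" = "CapEC2",
                     "CapIfn" = "CapIfn", "TrEC" = "TrEC",
                     "CRP" = "CRP", "CRP-early" = "CRP")

#' Configuration for the synthetic BEC atlas generator
#'
#' Defines the study conditions the generator plants: eleven blood endothelial
#' cell (BEC) subsets arranged on a three-branch vascular manifold, four
#' non-BEC contaminant classes, subset marker programs, a cell-cycle program
#' concentrated in CRP/CapEC1/TrEC, high UMI depth in high endothelial cells
#' (HEC), male/female cells, and technical batches.
#'
#' @param n_cells total number of cells (BEC plus contaminants).
#' @param n_genes number of genes; must cover the program demand.
#' @param subset_proportions named fractions over the 11 BEC subsets; must
#'   sum to 1.
#' @param contaminant_proportions named fractions of *all* cells per
#'   contaminant class (LEC, pericyte, FRC, lymphocyte).
#' @param marker_program_size marker genes per subset program.
#' @param depth_means named mean UMI depth per subset; the HEC subsets must
#'   exceed every non-HEC subset.
#' @param contaminant_depth mean UMI depth of contaminant cells.
#' @param division_propensity named probability per subset that a cell
#'   carries the cell-cycle program.
#' @param male_fraction fraction of male cells.
#' @param n_batches number of technical batches.
#' @param batch_shift_sd sd of the per-gene log-scale batch shift.
#' @param dispersion negative binomial size (inverse overdispersion); `Inf`
#'   gives the Poisson limit.
#' @param dropout_logit_slope,dropout_logit_intercept logistic dropout on the
#'   log mean: keep probability `plogis(intercept + slope * log(mu))`.
#' @param dropout whether dropout thinning is applied.
#' @param seed master seed for the generator.
#' @return An `atlas_config` list, validated.
#' @export
atlas_config <- function(
    n_cells = 5000,
    n_genes = 2000,
    subset_proportions = c(
      "Art" = 0.09, "pre-Art" = 0.07, "HEC" = 0.18, "HEC-late" = 0.06,
      "Vn" = 0.08, "CapEC1" = 0.10, "CapEC2" = 0.16, "CapIfn" = 0.04,
      "TrEC" = 0.08, "CRP" = 0.10, "CRP-early" = 0.04),
    contaminant_proportions = c(
      "LEC" = 0.015, "pericyte" = 0.010, "FRC" = 0.015,
      "lymphocyte" = 0.010),
    marker_program_size = 30,
    depth_means = c(
      "Art" = 5000, "pre-Art" = 5000, "HEC" = 12000, "HEC-late" = 10000,
      "Vn" = 6000, "CapEC1" = 4500, "CapEC2" = 4500, "CapIfn" = 5000,
      "TrEC" = 6000, "CRP" = 5000, "CRP-early" = 5000),
    contaminant_depth = 3000,
    division_propensity = c(
      "Art" = 0.005, "pre-Art" = 0.005, "HEC" = 0.005, "HEC-late" = 0.005,
      "Vn" = 0.005, "CapEC1" = 0.035, "CapEC2" = 0.005, "CapIfn" = 0.005,
      "TrEC" = 0.05, "CRP" = 0.12, "CRP-early" = 0.12),
    male_fraction = 0.5,
    n_batches = 2,
    batch_shift_sd = 0.15,
    dispersion = 10,
    dropout_logit_slope = 1.5,
    dropout_logit_intercept = 0.5,
    dropout = TRUE,
    seed = 1) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              subset_proportions = subset_proportions,
              contaminant_proportions = contaminant_proportions,
              marker_program_size = as.integer(marker_program_size),
              depth_means = depth_means,
              contaminant_depth = contaminant_depth,
              division_propensity = division_propensity,
              male_fraction = male_fraction, n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd, dispersion = dispersion,
              dropout_logit_slope = dropout_logit_slope,
              dropout_logit_intercept = dropout_logit_intercept,
              dropout = dropout, seed = as.integer(seed))
  class(cfg) <- "atlas_config"
  validate_atlas_config(cfg)
  cfg
}

validate_atlas_config <- function(cfg) {
  if (cfg$n_cells < 1 || cfg$n_genes < 1)
    stopf("n_cells and n_genes must be positive")
  sp <- cfg$subset_proportions
  if (!setequal(names(sp), BEC_SUBSETS))
    stopf("subset_proportions must name exactly the 11 BEC subsets")
  if (abs(sum(sp) - 1) > 1e-9)
    stopf("subset_proportions must sum to 1 (got %.12f)", sum(sp))
  cp <- cfg$contaminant_proportions
  if (!all(names(cp) %in% CONTAMINANT_CLASSES))
    stopf("unknown contaminant class: %s",
          setdiff(names(cp), CONTAMINANT_CLASSES)[1])
  if (sum(cp) >= 1) stopf("contaminant fractions must sum to < 1")
  dp <- cfg$division_propensity
  if (any(dp < 0 | dp > 1)) stopf("division propensities must be in [0,1]")
  dm <- cfg$depth_means
  if (!setequal(names(dm), BEC_SUBSETS)) stopf("depth_means incomplete")
  if (any(dm <= 0)) stopf("depth_means must be strictly positive")
  hec <- dm[c("HEC", "HEC-late")]
  if (min(hec) <= max(dm[setdiff(BEC_SUBSETS, c("HEC", "HEC-late"))]))
    stopf("HEC depth_means must exceed every non-HEC subset")
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1)
    stopf("male_fraction must be in [0,1]")
  if (cfg$batch_shift_sd < 0) stopf("batch_shift_sd must be non-negative")
  demand <- gene_program_demand(cfg)
  if (cfg$n_genes < demand)
    stopf("n_genes (%d) smaller than total program demand (%d)",
          cfg$n_genes, demand)
  invisible(cfg)
}

# genes consumed by planted programs: 11 marker programs, cycle program (40),
# Y-linked (6), Xist (1), 4 x 10 contaminant markers, venous GO set (15)
gene_program_demand <- function(cfg) {
  11L * cfg$marker_program_size + 40L + 6L + 1L + 40L + 15L
}

#' Preset emulating the full-size profiled dataset
#'
#' The desk-scale default uses 5,000 cells; this preset raises it to the
#' 8,832-cell scale of the profiled lymph-node BEC dataset.
#' @param ... overrides passed to [atlas_config()].
#' @return An `atlas_config`.
#' @export
atlas_config_full <- function(...) atlas_config(n_cells = 8832, ...)
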