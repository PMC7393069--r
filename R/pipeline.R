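#' Default end-to-end run configuration
#'
#' All stage parameters with their defaults: gene filter at 3 cells / 0.3
#' mean expression, clustering resolution 0.3, imputation (t = 2, k = 9,
#' ka = 3), entropy depth 1000 reads/cell, DE significance at adjusted
#' p < 0.001, top-50 signatures, 3000 variable genes.
#'
#' @param seed master seed fanned out to per-stage seeds by stable hashing
#'   of stage names, so toggling one stage does not shift the others'
#'   randomness.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    out_dir = NULL,
    stages = list(synthetic = TRUE, preprocess = TRUE, annotate = TRUE,
                  trajectory = TRUE, genescore = TRUE, impute = TRUE,
                  entropy = TRUE, diffexp = TRUE),
    synthetic = list(n_cells = 5000, n_genes = 2000),
    input = list(counts_dir = NULL),
    preprocess = list(min_cells = 3, min_mean = 0.3, hvg = 3000,
                      contaminant_threshold = 0.25, sex_delta = 0.1),
    annotate = list(resolution = 0.3, n_pcs = 20, snn_k = 20,
                    cycle_tau = 0.1, subdivide_q = 0.5),
    trajectory = list(knn = 20, n_tpc = 5, smooth_h = 0.05, grid_n = 200),
    genescore = list(n_bins = 24, n_ctrl = 100, alpha = 0.001),
    impute = list(t = 2, k = 9, ka = 3),
    entropy = list(depth = 1000, network_genes = 300, top_frac = 0.01),
    diffexp = list(alpha = 0.001, top = 50, max_genes = 150))
}

check_config_keys <- function(config, defaults, path = "") {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra))
    stopf("unknown configuration key(s): %s",
          paste0(path, extra, collapse = ", "))
  for (k in names(config))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      check_config_keys(config[[k]], defaults[[k]], paste0(path, k, "."))
}

merge_config <- function(defaults, override) {
  for (k in names(override)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) &&
                           !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], override[[k]]) else override[[k]]
  }
  defaults
}

write_stage_tsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the configured pipeline end to end
#'
#' Executes synthetic-data generation (or count ingest), preprocessing,
#' clustering and annotation, trajectory inference, gene-set scoring,
#' imputation, entropy and differential expression as toggled, writing each
#' stage's artifacts and an md5 run report under the output directory.
#' Identical configuration and seed reproduce identical artifact hashes.
#'
#' @param config nested list as produced by [default_run_config()], a
#'   partial override of it, or a path to a YAML file with the same
#'   structure. Unknown keys are rejected.
#' @return invisible list of in-memory stage results plus `report` (artifact
#'   md5 table) and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  check_config_keys(config, defaults)
  cfg <- merge_config(defaults, config)
  out_dir <- cfg$out_dir %||% tempfile("becatlas_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  res <- list()
  seed_of <- function(stage) derive_seed(cfg$seed, stage)

  # --- data ----------------------------------------------------------------
  if (isTRUE(cfg$stages$synthetic)) {
    acfg <- atlas_config(n_cells = cfg$synthetic$n_cells,
                         n_genes = cfg$synthetic$n_genes,
                         seed = seed_of("synthetic"))
    atlas <- generate_atlas(acfg)
    write_atlas(atlas, file.path(out_dir, "atlas"))
    artifacts <- c(artifacts, file.path(out_dir, "atlas", "matrix.mtx"))
    res$atlas <- atlas
    counts <- atlas$counts
    programs <- atlas$programs
  } else {
    if (is.null(cfg$input$counts_dir)) stopf("no input counts configured")
    counts <- read_counts(cfg$input$counts_dir)
    programs <- NULL
    res$counts <- counts
  }
  program_sets <- function(progs) {
    sets <- split(programs$gene_id, programs$program)
    gene_sets(sets[progs])
  }

  # --- preprocess ----------------------------------------------------------
  if (isTRUE(cfg$stages$preprocess)) {
    bec_log("pipeline", "stage preprocess")
    norm <- normalize_counts(counts)
    if (!is.null(programs)) {
      sigs <- program_sets(paste0("contaminant_", CONTAMINANT_CLASSES))
      names(sigs) <- sub("contaminant_", "", names(sigs))
      rc <- remove_contaminants(norm, sigs,
                                threshold = cfg$preprocess$contaminant_threshold,
                                seed = seed_of("contaminants"))
      norm <- rc$norm
    }
    res$norm_prefilter <- norm   # cycle classification uses unfiltered genes
    fg <- filter_genes(norm, counts, min_cells = cfg$preprocess$min_cells,
                       min_mean = cfg$preprocess$min_mean)
    norm <- fg$norm
    # cycle and sex-linked genes are kept out of the clustering features;
    # division and sex are annotated separately
    drop_feats <- if (!is.null(programs))
      programs$gene_id[programs$program %in% c("cycle", "Y", "Xist")]
      else character(0)
    hvg <- select_hvg(norm, cfg$preprocess$hvg, exclude = drop_feats)
    if (!is.null(programs)) {
      sex <- demux_sex(norm, programs$gene_id[programs$program == "Y"],
                       programs$gene_id[programs$program == "Xist"],
                       delta = cfg$preprocess$sex_delta,
                       seed = seed_of("sex"))
      artifacts <- c(artifacts, write_stage_tsv(sex, out_dir, "sex_calls"))
      res$sex <- sex
    }
    writeLines(hvg, file.path(out_dir, "hvg.txt"))
    artifacts <- c(artifacts, file.path(out_dir, "hvg.txt"))
    res$norm <- norm; res$hvg <- hvg
  }

  # --- annotate ------------------------------------------------------------
  if (isTRUE(cfg$stages$annotate)) {
    bec_log("pipeline", "stage annotate")
    norm <- res$norm
    pcs <- pca_embed(norm$values, intersect(res$hvg, rownames(norm$values)),
                     cfg$annotate$n_pcs, seed = seed_of("pca"))
    batches <- norm$cell_meta$batch %||% rep("batch1", ncol(norm$values))
    if (length(unique(batches)) > 1) {
      blist <- lapply(unique(batches), function(b)
        pcs[batches == b, , drop = FALSE])
      al <- mnn_align(blist)
      pcs[unlist(lapply(unique(batches), function(b)
        which(batches == b))), ] <- al$corrected
    }
    cycle_genes <- programs$gene_id[programs$program == "cycle"]
    dividing <- classify_cycle(res$norm_prefilter, cycle_genes,
                               tau = cfg$annotate$cycle_tau,
                               seed = seed_of("cycle"))
    pcs_cc <- remove_cycle_effect(pcs, dividing)
    clusters <- cluster_core(norm, NULL, resolution = cfg$annotate$resolution,
                             k = cfg$annotate$snn_k,
                             seed = seed_of("cluster"), pcs = pcs_cc)
    major_sets <- program_sets(BEC_SUBSETS)
    majors_of <- MAJOR_OF_SUBSET[names(major_sets)]
    merged <- lapply(split(seq_along(major_sets), majors_of), function(i)
      unique(unlist(major_sets[i])))
    majors <- annotate_majors(norm, clusters, gene_sets(merged),
                              seed = seed_of("majors"))
    res$pcs <- pcs_cc; res$clusters <- clusters; res$majors <- majors
    res$dividing <- dividing
  }

  # --- trajectory + subdivision -------------------------------------------
  if (isTRUE(cfg$stages$trajectory)) {
    bec_log("pipeline", "stage trajectory")
    traj <- tspace(res$pcs, k = cfg$trajectory$knn,
                   seed = seed_of("tspace"), n_tpc = cfg$trajectory$n_tpc)
    # root: most CRP-early-like cells of the CRP major cluster
    ce_score <- module_score(res$norm,
                             programs$gene_id[programs$program == "CRP-early"],
                             seed = seed_of("root"))
    crp_cells <- names(res$clusters)[res$majors == "CRP"]
    root <- crp_cells[order(-ce_score[match(crp_cells,
                                            colnames(res$norm$values))])]
    root <- head(root, max(5, round(0.1 * length(root))))
    rd <- root_distance(traj, root)
    labels11 <- subdivide_termini(res$majors, rd,
                                  q = cfg$annotate$subdivide_q)
    lab_df <- data.frame(cell_id = colnames(res$norm$values),
                         major = res$majors, subset = labels11,
                         is_dividing = unname(res$dividing),
                         root_distance = unname(rd))
    artifacts <- c(artifacts, write_stage_tsv(lab_df, out_dir, "labels"))
    res$traj <- traj; res$labels <- labels11; res$root <- root
  }

  # --- gene-set scores -----------------------------------------------------
  if (isTRUE(cfg$stages$genescore)) {
    bec_log("pipeline", "stage genescore")
    sets <- program_sets(c(BEC_SUBSETS, "go_venous"))
    sm <- score_all_sets(res$norm, sets, n_bins = cfg$genescore$n_bins,
                         n_ctrl = cfg$genescore$n_ctrl,
                         seed = seed_of("scores"))
    screen <- go_screen(sm, res$labels, alpha = cfg$genescore$alpha)
    artifacts <- c(artifacts, write_stage_tsv(screen, out_dir, "go_screen"))
    res$score_matrix <- sm; res$go_screen <- screen
  }

  # --- imputation ----------------------------------------------------------
  if (isTRUE(cfg$stages$impute)) {
    bec_log("pipeline", "stage impute")
    graph <- build_markov(res$pcs, k = cfg$impute$k, ka = cfg$impute$ka)
    res$imputed <- impute_expression(res$norm, graph, t = cfg$impute$t)
  }

  # --- entropy -------------------------------------------------------------
  if (isTRUE(cfg$stages$entropy)) {
    bec_log("pipeline", "stage entropy")
    hub <- programs$gene_id[programs$program %in% c("CRP", "CRP-early")]
    net_genes <- union(hub, head(programs$gene_id[
      programs$program == "housekeeping"],
      cfg$entropy$network_genes - length(hub)))
    net <- sample_scale_free_network(net_genes, m = 3,
                                     seed = seed_of("network"),
                                     hub_genes = hub)
    keep_cells <- colnames(res$norm$values)
    ci <- match(keep_cells, counts$cell_ids)
    sub_counts <- count_matrix(counts$counts[, ci], counts$gene_ids,
                               keep_cells,
                               counts$cell_meta[ci, , drop = FALSE])
    ent <- entropy_pipeline(sub_counts, net, depth = cfg$entropy$depth,
                            seed = seed_of("entropy"),
                            top_frac = cfg$entropy$top_frac)
    artifacts <- c(artifacts, write_stage_tsv(ent, out_dir, "entropy"))
    res$entropy <- ent
  }

  # --- differential expression --------------------------------------------
  if (isTRUE(cfg$stages$diffexp)) {
    bec_log("pipeline", "stage diffexp")
    # a representative slice of the gene space keeps the demo stage fast:
    # a fixed number of marker genes per subset plus housekeeping background
    per_subset <- max(2, floor(cfg$diffexp$max_genes / 15))
    marker_genes <- unlist(lapply(BEC_SUBSETS, function(s)
      head(programs$gene_id[programs$program == s], per_subset)))
    hk <- head(programs$gene_id[programs$program == "housekeeping"],
               cfg$diffexp$max_genes - length(marker_genes))
    test_genes <- intersect(c(marker_genes, hk), rownames(res$norm$values))
    keep_cells <- colnames(res$norm$values)
    ci <- match(keep_cells, counts$cell_ids)
    sub_counts <- count_matrix(counts$counts[, ci], counts$gene_ids,
                               keep_cells,
                               counts$cell_meta[ci, , drop = FALSE])
    de <- de_all(sub_counts, res$labels,
                 size_factors = res$norm$size_factors,
                 genes = test_genes, alpha = cfg$diffexp$alpha)
    sig <- de_signatures(de, n = cfg$diffexp$top)
    artifacts <- c(artifacts, write_stage_tsv(de, out_dir, "de_results"))
    res$de <- de; res$signatures <- sig
  }

  report <- data.frame(artifact = basename(artifacts),
                       md5 = unname(tools::md5sum(artifacts)),
                       stringsAsFactors = FALSE)
  write_stage_tsv(report, out_dir, "run_report")
  res$report <- report
  res$out_dir <- out_dir
  invisible(res)
}
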