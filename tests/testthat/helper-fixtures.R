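# Shared fixtures, built lazily once per test run. The "flow" fixture runs
# the standard preprocessing chain (normalize -> contaminant removal ->
# cycle classification -> gene filter -> HVG -> PCA -> MNN batch alignment
# -> cycle-effect removal) on a mid-sized synthetic atlas.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2)); e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

program_gene_sets <- function(programs, names) {
  sets <- split(programs$gene_id, programs$program)[names]
  gene_sets(sets)
}

contaminant_sigs <- function(programs) {
  s <- program_gene_sets(programs, paste0("contaminant_", c(
    "LEC", "pericyte", "FRC", "lymphocyte")))
  names(s) <- sub("contaminant_", "", names(s))
  s
}

run_standard_flow <- function(n_cells, seed, hvg_n = 800) {
  a <- generate_atlas(atlas_config(n_cells = n_cells, seed = seed))
  norm_full <- suppressMessages(normalize_counts(a$counts))
  progs <- a$programs
  rc <- suppressMessages(remove_contaminants(norm_full,
                                             contaminant_sigs(progs),
                                             seed = seed + 1))
  norm_full <- rc$norm
  cyc <- progs$gene_id[progs$program == "cycle"]
  dividing <- classify_cycle(norm_full, cyc, seed = seed + 2)
  fg <- suppressMessages(filter_genes(norm_full, a$counts))
  norm <- fg$norm
  drop_feats <- progs$gene_id[progs$program %in% c("cycle", "Y", "Xist")]
  hvg <- select_hvg(norm, hvg_n, exclude = drop_feats)
  truth <- a$truth[match(colnames(norm$values), a$truth$cell_id), ]
  pcs <- becatlas:::pca_embed(norm$values, hvg, 20, seed = seed + 3)
  bt <- truth$batch
  blist <- lapply(unique(bt), function(b) pcs[bt == b, , drop = FALSE])
  al <- suppressMessages(mnn_align(blist))
  pcs[unlist(lapply(unique(bt), function(b) which(bt == b))), ] <-
    al$corrected
  pcs <- suppressMessages(remove_cycle_effect(pcs, unname(dividing)))
  list(atlas = a, programs = progs, norm = norm, norm_prefilter = norm_full,
       dividing = dividing, hvg = hvg, truth = truth, pcs = pcs)
}

# main shared fixture: 2,000 cells, seed 4
flow2000 <- function() memo("flow2000", function()
  run_standard_flow(2000, seed = 4))

# smaller raw atlas for entropy and panel tests
atlas1200 <- function() memo("atlas1200", function()
  generate_atlas(atlas_config(n_cells = 1200, seed = 6)))

# trajectory space over the flow2000 embedding
traj2000 <- function() memo("traj2000", function() {
  f <- flow2000()
  suppressMessages(tspace(f$pcs, k = 20, seed = 12))
})

# hub-anchored root cells and distances for flow2000
rootdist2000 <- function() memo("rootdist2000", function() {
  f <- flow2000()
  hub_sc <- module_score(f$norm,
                         f$programs$gene_id[f$programs$program == "cap_hub"],
                         seed = 2)
  root <- head(colnames(f$norm$values)[order(-hub_sc)], 25)
  becatlas:::root_distance(traj2000(), root)
})
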