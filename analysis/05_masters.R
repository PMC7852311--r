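#!/usr/bin/env Rscript
# The master-regulator layer: mutation-frequency filters, PPI coverage of
# the module TFs, cross-tumor summary, cluster-level regulator extraction
# with a linear SVM, and pathway over-representation with the
# mutational-activation flag.

source("analysis/00_settings.R")

sim <- get_study()
pipe <- get_pipeline(sim)
fin <- pipe$modules[pipe$modules$final, ]

masters <- lapply(sim$truth$tumors, function(t)
  link_masters(filter_drivers(sim$drivers, t), sim$ppi,
               unique(fin$tf[fin$tumor == t]), t))
names(masters) <- sim$truth$tumors
write_tsv(do.call(rbind, masters), file.path(RESULTS_DIR, "masters.tsv"))

s <- regulator_summary(masters)
write_tsv(s$per_tumor, file.path(RESULTS_DIR, "masters_per_tumor.tsv"))
message(sprintf("masters per tumor: %.1f on average (%.1f tumor-specific); %.1f TFs per master",
                s$avg_total, s$avg_specific, s$tf_per_master))
message("common regulators (>= 2 tumors): ", paste(s$common, collapse = ", "))

# cluster-level extraction: tumors sharing a common regulator
occ <- table(unlist(lapply(masters, function(m) unique(m$driver))))
shared_gene <- names(occ)[occ >= 2][1]
members <- names(Filter(function(m) shared_gene %in% m$driver, masters))
sel <- cluster_regulator_selection(masters, sim$expr, sim$annotation,
                                   members, seed = STUDY_SEED)
message(sprintf("linear-SVM separation of {%s} vs rest on shared regulators {%s}: AUC %.3f",
                paste(members, collapse = ", "),
                paste(sel$regulators, collapse = ", "), sel$auc))
write_tsv(data.frame(regulator = sel$regulators,
                     importance = unname(sel$importance), auc = sel$auc),
          file.path(RESULTS_DIR, "cluster_regulators.tsv"))

# synthetic pathway table: one pathway per tumor built over its regulatory
# layer (masters + module TFs) plus size-matched random decoy pathways
set.seed(STUDY_SEED)
universe <- rownames(sim$expr)
pathways <- lapply(sim$truth$tumors, function(t)
  unique(c(masters[[t]]$driver, fin$tf[fin$tumor == t])))
names(pathways) <- paste0("regulatory_", sim$truth$tumors)
decoys <- lapply(1:5, function(i) sample(universe, 10))
names(decoys) <- paste0("decoy_", 1:5)
pathways <- c(pathways, decoys)

t1 <- sim$truth$tumors[1]
query <- unique(c(masters[[t1]]$driver, fin$tf[fin$tumor == t1]))
spec_m <- masters[[t1]]$driver[masters[[t1]]$driver_class == "tumor-specific"]
enr <- pathway_enrichment(query, pathways, universe,
                          specific_masters = spec_m)
write_tsv(enr, file.path(RESULTS_DIR, "pathway_enrichment.tsv"))
message(sprintf("top pathway for %s: %s (FDR %.3g, mutationally activated: %s)",
                t1, enr$pathway[1], enr$fdr[1], enr$mutationally_activated[1]))
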