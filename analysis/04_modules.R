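#!/usr/bin/env Rscript
# The consensus module engine: mine TF-target candidates from the prior
# sources, filter by correlation separation (Fisher z + Youden threshold),
# prune with the adaptive lasso, confirm with the sparse Gaussian network
# and lasso neighborhood selection, keep the two-of-three consensus, and
# cross-validate the surviving proteins against staining profiles.

source("analysis/00_settings.R")

sim <- get_study()
pipe <- get_pipeline(sim)

counts <- t(sapply(pipe$results, function(r) r$counts))
write_tsv(data.frame(tumor_type = rownames(counts), counts),
          file.path(RESULTS_DIR, "module_stage_counts.tsv"))
message("stage-by-stage module counts (rows shrink monotonically):")
print(counts)

mods <- pipe$modules
write_tsv(mods[, c("tf", "target", "tumor", "sources", "r_in", "r_rest",
                   "zcor_in", "zcor_rest", "in_model1", "in_model2",
                   "in_model3", "final")],
          file.path(RESULTS_DIR, "modules.tsv"))

fin <- mods[mods$final, ]
ev <- evaluate_module_recovery(fin, sim$truth)
message(sprintf("final modules: %d; recovery vs planted truth: precision %.3f, recall %.3f",
                nrow(fin), ev$precision, ev$recall))
message(sprintf("in-tumor vs rest-of-cohort correlation of final modules: mean r_in %.2f vs mean r_rest %.2f",
                mean(fin$r_in), mean(fin$r_rest)))

pps <- staining_crossval(fin, sim$staining)
write_tsv(pps, file.path(RESULTS_DIR, "staining_validation.tsv"))
message(sprintf("staining cross-validation: %d/%d assayed proteins validated (PPS > 0)",
                sum(pps$validated, na.rm = TRUE), sum(pps$assayed)))
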