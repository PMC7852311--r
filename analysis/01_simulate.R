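#!/usr/bin/env Rscript
# Generate the reference synthetic pan-cancer study: a 5-tumor cohort with
# matched healthy tissues, planted matrisome signatures, TF-target modules,
# master regulators and prognostic effects, plus all the side tables
# (priors, drivers, PPI, staining, drugs) the downstream stages consume.

source("analysis/00_settings.R")

sim <- get_study()
write_simulation(sim, file.path(RESULTS_DIR, "simulation"))

ann <- sim$annotation
message(sprintf("cohort: %d genes x %d samples (%d tumor, %d healthy), %d tumor types",
                nrow(sim$expr), ncol(sim$expr),
                sum(ann$sample_class != "healthy"),
                sum(ann$sample_class == "healthy"),
                length(sim$truth$tumors)))
message(sprintf("planted: %d signature genes, %d modules, %d masters per tumor",
                length(sim$truth$planted_signatures[[1]]),
                nrow(sim$truth$planted_modules[[1]]),
                nrow(sim$truth$planted_masters[[1]])))
message(sprintf("priors: %d (tf, target, source) rows over %d distinct pairs",
                nrow(sim$priors),
                nrow(unique(sim$priors[, c("tf", "target")]))))
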