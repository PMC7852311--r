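#!/usr/bin/env Rscript
# Prognostic value and druggability: per-module Kaplan-Meier/log-rank on
# mean-dichotomized module activity, the direction-consistency check, and
# the layered on/off-label drug mapping.

source("analysis/00_settings.R")

sim <- get_study()
pipe <- get_pipeline(sim)
fin <- pipe$modules[pipe$modules$final, ]

surv <- do.call(rbind, lapply(sim$truth$tumors, function(t) {
  mods <- fin[fin$tumor == t, ]
  if (nrow(mods) == 0) return(NULL)
  module_survival_screen(mods, sim$expr, sim$annotation, t)
}))
write_tsv(surv, file.path(RESULTS_DIR, "module_survival.tsv"))
sig <- surv[surv$p_value < 0.05, ]
message(sprintf("%d of %d modules associate with survival at P < 0.05 (%d noxious, %d favorable)",
                nrow(sig), nrow(surv),
                sum(sig$direction == "noxious", na.rm = TRUE),
                sum(sig$direction == "favorable", na.rm = TRUE)))
planted <- do.call(rbind, lapply(names(sim$truth$planted_prognostic),
                                 function(t) cbind(sim$truth$planted_prognostic[[t]],
                                                   tumor = t)))
key <- paste(surv$tumor, surv$tf, surv$target)
pk <- paste(planted$tumor, planted$tf, planted$target)
hit <- surv$p_value < 0.05 &
  surv$direction == planted$direction[match(key, pk)]
message(sprintf("planted prognostic modules recovered with direction: %d/%d",
                sum(hit[key %in% pk], na.rm = TRUE), nrow(planted)))

for (t in sim$truth$tumors) {
  dc <- direction_consistency(surv, t)
  if (!dc$consistent) {
    message(t, ": direction-consistency violations at ",
            paste(dc$violations$hub, collapse = ", "))
  }
}
message("direction consistency holds in all tumors: ",
        all(sapply(sim$truth$tumors,
                   function(t) direction_consistency(surv, t)$consistent)))

drugs <- load_drug_interactions(sim$drugs)
drug_report <- do.call(rbind, lapply(sim$truth$tumors, function(t) {
  masters <- link_masters(filter_drivers(sim$drivers, t), sim$ppi,
                          unique(fin$tf[fin$tumor == t]), t)
  arch <- list(matrisome = pipe$signatures[[t]]$genes,
               tfs = unique(fin$tf[fin$tumor == t]),
               masters = masters$driver)
  rep <- suppressWarnings(map_druggability(arch, drugs, t))
  if (nrow(rep)) cbind(tumor = t, rep) else NULL
}))
write_tsv(drug_report, file.path(RESULTS_DIR, "druggability.tsv"))
message(sprintf("druggability rows by layer: %s",
                paste(names(table(drug_report$layer)),
                      table(drug_report$layer), sep = "=", collapse = ", ")))
message(sprintf("FDA cancer drugs: %d on-label, %d off-label rows",
                sum(drug_report$label_status == "on-label", na.rm = TRUE),
                sum(drug_report$label_status == "off-label", na.rm = TRUE)))
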