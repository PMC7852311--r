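# Shared settings for the analysis scripts: one master seed and the
# reference synthetic study, regenerated deterministically so every script
# can be run on its own.

library(matreg)

STUDY_SEED <- 1L
RESULTS_DIR <- "results"

get_study <- function() simulate_study(sim_config(seed = STUDY_SEED))

get_pipeline <- function(sim = get_study()) {
  run_study_pipeline(sim, seed = STUDY_SEED)
}

write_tsv <- function(x, file) {
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", file)
}
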