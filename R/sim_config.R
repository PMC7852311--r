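#' Simulation configuration for the synthetic multi-tumor cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults define the reference study conditions used throughout the
#' package's tests and analyses: 5 tumor types of 200 samples each with 50
#' matched healthy samples per tissue, planted TF-target modules with
#' in-tumor Pearson correlation 0.8 against 0.1 elsewhere, +4 log2-unit
#' signature shifts, 3 decoy prior pairs per true pair, and a planted
#' prognostic hazard ratio of 3.
#'
#' @param n_tumor_types number of tumor types in the cohort.
#' @param samples_per_tumor primary-tumor samples per tumor type.
#' @param healthy_per_tissue matched healthy samples per tumor type.
#' @param n_genes total genes in the expression matrix.
#' @param n_matrisome number of matrisome genes (must be <= `n_genes`).
#' @param n_tfs number of transcription factors, disjoint from the matrisome
#'   (must be <= `n_genes - n_matrisome`).
#' @param planted_modules_per_tumor true TF-target modules planted per tumor;
#'   module targets are drawn from that tumor's planted signature, so this
#'   must not exceed `signature_genes_per_tumor`.
#' @param r_in planted Pearson correlation of a module pair inside its owning
#'   tumor, in \[0, 1).
#' @param r_out correlation of the same pair in every other sample group;
#'   must be strictly below `r_in`.
#' @param signature_genes_per_tumor matrisome genes up-shifted per tumor.
#' @param signature_log2_shift up-regulation of signature genes in their
#'   owning tumor, in log2 units.
#' @param prior_coverage probability that a true module is listed by each
#'   individual prior source (coverage is then repaired so that every true
#'   module keeps at least two sources, one of them FANTOM5-like).
#' @param decoy_rate number of false prior pairs generated per true pair.
#' @param driver_freq_specific mutation frequency given to planted
#'   tumor-specific master regulators (the default 0.15 clears the 5%
#'   driver filter with a wide margin).
#' @param hazard_ratio_prognostic hazard ratio applied to samples on the
#'   risk side of a planted prognostic module; 1 disables the effect.
#' @param censoring_rate probability that a survival time is censored.
#' @param seed integer master seed; each generator stage derives its own
#'   substream from it, so regenerating one table does not perturb others.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_tumor_types = 5,
                       samples_per_tumor = 200,
                       healthy_per_tissue = 50,
                       n_genes = 300,
                       n_matrisome = 120,
                       n_tfs = 60,
                       planted_modules_per_tumor = 8,
                       r_in = 0.8,
                       r_out = 0.1,
                       signature_genes_per_tumor = 12,
                       signature_log2_shift = 4,
                       prior_coverage = 0.8,
                       decoy_rate = 3,
                       driver_freq_specific = 0.15,
                       hazard_ratio_prognostic = 3,
                       censoring_rate = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_tumor_types = as.integer(n_tumor_types),
    samples_per_tumor = as.integer(samples_per_tumor),
    healthy_per_tissue = as.integer(healthy_per_tissue),
    n_genes = as.integer(n_genes),
    n_matrisome = as.integer(n_matrisome),
    n_tfs = as.integer(n_tfs),
    planted_modules_per_tumor = as.integer(planted_modules_per_tumor),
    r_in = r_in,
    r_out = r_out,
    signature_genes_per_tumor = as.integer(signature_genes_per_tumor),
    signature_log2_shift = signature_log2_shift,
    prior_coverage = prior_coverage,
    decoy_rate = as.integer(decoy_rate),
    driver_freq_specific = driver_freq_specific,
    hazard_ratio_prognostic = hazard_ratio_prognostic,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of a [sim_config()] and stops with a
#' message naming the first violated one.
#'
#' @param config a `"sim_config"` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- c("n_tumor_types", "samples_per_tumor", "healthy_per_tissue",
              "n_genes", "n_matrisome", "n_tfs",
              "planted_modules_per_tumor", "signature_genes_per_tumor")
  for (nm in counts) {
    if (is.na(config[[nm]]) || config[[nm]] < 1L) {
      stop("invalid sim_config: count '", nm, "' must be >= 1", call. = FALSE)
    }
  }
  if (config$decoy_rate < 0L) {
    stop("invalid sim_config: 'decoy_rate' must be >= 0", call. = FALSE)
  }
  probs <- c("prior_coverage", "censoring_rate")
  for (nm in probs) {
    if (config[[nm]] < 0 || config[[nm]] > 1) {
      stop("invalid sim_config: probability '", nm, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (config$driver_freq_specific < 0 || config$driver_freq_specific > 1) {
    stop("invalid sim_config: 'driver_freq_specific' must lie in [0, 1]",
         call. = FALSE)
  }
  if (config$r_in < 0 || config$r_in >= 1) {
    stop("invalid sim_config: 'r_in' must lie in [0, 1)", call. = FALSE)
  }
  if (config$r_out < 0 || config$r_out >= 1) {
    stop("invalid sim_config: 'r_out' must lie in [0, 1)", call. = FALSE)
  }
  if (config$r_out >= config$r_in) {
    stop("invalid sim_config: 'r_out' must be strictly below 'r_in'",
         call. = FALSE)
  }
  if (config$hazard_ratio_prognostic <= 0) {
    stop("invalid sim_config: 'hazard_ratio_prognostic' must be > 0",
         call. = FALSE)
  }
  if (config$n_matrisome > config$n_genes) {
    stop("invalid sim_config: 'n_matrisome' must be <= 'n_genes'",
         call. = FALSE)
  }
  if (config$n_tfs > config$n_genes - config$n_matrisome) {
    stop("invalid sim_config: 'n_tfs' must be <= 'n_genes' - 'n_matrisome'",
         call. = FALSE)
  }
  if (config$signature_genes_per_tumor * config$n_tumor_types >
      config$n_matrisome) {
    stop("invalid sim_config: planted signatures must fit in the matrisome ",
         "('signature_genes_per_tumor' * 'n_tumor_types' <= 'n_matrisome')",
         call. = FALSE)
  }
  if (config$planted_modules_per_tumor > config$signature_genes_per_tumor) {
    stop("invalid sim_config: 'planted_modules_per_tumor' must be <= ",
         "'signature_genes_per_tumor' (module targets are signature genes)",
         call. = FALSE)
  }
  if (config$planted_modules_per_tumor > config$n_tfs) {
    stop("invalid sim_config: 'planted_modules_per_tumor' must be <= 'n_tfs'",
         call. = FALSE)
  }
  if (config$seed < 0L || config$seed > .Machine$integer.max - 10L) {
    stop("invalid sim_config: 'seed' must be a non-negative 32-bit integer",
         call. = FALSE)
  }
  invisible(config)
}

# Stage-specific substream seeds derived from the master seed, so each
# generator stage has its own reproducible random stream.
stage_seed <- function(config, stage) {
  offsets <- c(cohort = 0L, priors = 1L, driver_ppi = 2L,
               survival = 3L, staining_drugs = 4L)
  if (!stage %in% names(offsets)) stop("unknown generator stage: ", stage)
  config$seed + offsets[[stage]]
}

#' The seven matrisome gene categories
#'
#' @return Character vector of category names.
#' @export
matrisome_categories <- function() {
  c("basement membranes", "collagens", "ECM-affiliated", "ECM glycoproteins",
    "ECM regulators", "proteoglycans", "secreted factors")
}
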