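#' Generate a synthetic multi-tumor expression cohort with planted structure
#'
#' Builds a genes x samples expression matrix on the log2(x+1) scale,
#' emulating an RSEM-quantified, upper-quantile-normalized pan-cancer
#' compendium with matched healthy tissues. Per-(gene, tumor) baseline means
#' are drawn once from a shared hyper-distribution so tumor types are
#' separable; planted signature genes are shifted up by
#' `signature_log2_shift` in their owning tumor only; planted TF-target
#' module pairs are constructed with Pearson correlation about `r_in` inside
#' the owning tumor and about `r_out` in every other sample group, via a
#' shared-latent-factor construction (target = a * z_TF + sqrt(1 - a^2) *
#' noise on the standardized scale, with a equal to the requested r).
#'
#' The returned ground truth names the planted signatures, modules, master
#' regulators and prognostic modules; downstream generators
#' ([generate_priors()], [generate_driver_ppi()], [generate_survival()],
#' [generate_staining_drugs()]) honor it, and recovery tests use it as the
#' oracle.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{expr}{numeric matrix, genes x samples, log2-scale, non-negative.}
#'     \item{annotation}{data.frame with one row per sample: `sample_id`,
#'       `tumor_type`, `system_of_origin`, `sample_class` (primary/healthy);
#'       survival fields are filled by [generate_survival()].}
#'     \item{matrisome}{data.frame `gene_id`, `category`.}
#'     \item{truth}{list with `planted_signatures`, `planted_modules`,
#'       `planted_masters`, `planted_prognostic`, plus the gene pools.}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "cohort"))

  tumors <- sprintf("T%02d", seq_len(config$n_tumor_types))
  systems <- c("digestive", "respiratory", "urogenital", "nervous",
               "endocrine", "hematologic", "integumentary")
  system_of <- stats::setNames(
    systems[(seq_along(tumors) - 1L) %% length(systems) + 1L], tumors)

  mat_genes <- sprintf("MAT%03d", seq_len(config$n_matrisome))
  tf_genes <- sprintf("TF%03d", seq_len(config$n_tfs))
  n_other <- config$n_genes - config$n_matrisome - config$n_tfs
  other_genes <- if (n_other > 0) sprintf("OTH%03d", seq_len(n_other)) else character()
  genes <- c(mat_genes, tf_genes, other_genes)

  matrisome <- data.frame(
    gene_id = mat_genes,
    category = matrisome_categories()[
      (seq_along(mat_genes) - 1L) %% 7L + 1L],
    stringsAsFactors = FALSE
  )

  # sample ids and annotation
  tumor_ids <- unlist(lapply(tumors, function(t)
    sprintf("%s.S%03d", t, seq_len(config$samples_per_tumor))))
  healthy_ids <- unlist(lapply(tumors, function(t)
    sprintf("%s.H%03d", t, seq_len(config$healthy_per_tissue))))
  annotation <- data.frame(
    sample_id = c(tumor_ids, healthy_ids),
    tumor_type = c(rep(tumors, each = config$samples_per_tumor),
                   rep(tumors, each = config$healthy_per_tissue)),
    system_of_origin = c(
      system_of[rep(tumors, each = config$samples_per_tumor)],
      system_of[rep(tumors, each = config$healthy_per_tissue)]),
    sample_class = c(rep("primary", length(tumor_ids)),
                     rep("healthy", length(healthy_ids))),
    survival_days = NA_real_,
    event = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(annotation) <- NULL

  # baseline means: gene-level center + per-(gene, group) deviation from a
  # shared hyper-distribution; healthy tissues get their own draw
  # gene-level centers plus per-(gene, tumor) deviations; the deviation
  # scale exceeds the center scale so unrelated tumor types decorrelate
  # (mean-vector Pearson r well below 0.5) and separate at the default cut
  mu_gene <- stats::runif(length(genes), min = 4, max = 8)
  names(mu_gene) <- genes
  groups <- c(stats::setNames(tumors, tumors),
              stats::setNames(paste0(tumors, ".healthy"), paste0(tumors, ".healthy")))
  mu_group <- sapply(tumors, function(g) mu_gene + stats::rnorm(length(genes), 0, 1.5))
  # matched healthy tissue shares its tumor's baseline means, so with no
  # planted shift a tumor and its healthy tissue differ only by sampling noise
  mu_group <- cbind(mu_group, mu_group)
  colnames(mu_group) <- groups
  rownames(mu_group) <- genes

  # planted signatures: disjoint blocks of matrisome genes per tumor
  sig_idx <- split(
    seq_len(config$signature_genes_per_tumor * config$n_tumor_types),
    rep(seq_len(config$n_tumor_types), each = config$signature_genes_per_tumor))
  planted_signatures <- lapply(sig_idx, function(ix) mat_genes[ix])
  names(planted_signatures) <- tumors

  # planted modules: targets from the tumor's signature; TFs sampled without
  # replacement within a tumor so each target has exactly one planted TF
  planted_modules <- lapply(tumors, function(t) {
    targets <- planted_signatures[[t]][seq_len(config$planted_modules_per_tumor)]
    tfs <- sample(tf_genes, config$planted_modules_per_tumor, replace = FALSE)
    data.frame(tf = tfs, target = targets, stringsAsFactors = FALSE)
  })
  names(planted_modules) <- tumors

  # expression: baseline noise around the group mean, sd 1, clamped at 0
  n_samples <- nrow(annotation)
  group_of_sample <- ifelse(annotation$sample_class == "healthy",
                            paste0(annotation$tumor_type, ".healthy"),
                            annotation$tumor_type)
  expr <- matrix(NA_real_, nrow = length(genes), ncol = n_samples,
                 dimnames = list(genes, annotation$sample_id))
  for (g in groups) {
    cols <- which(group_of_sample == g)
    expr[, cols] <- mu_group[, g] +
      matrix(stats::rnorm(length(genes) * length(cols)), length(genes))
  }

  # signature shift: owning tumor's primary samples only
  for (t in tumors) {
    cols <- which(group_of_sample == t)
    expr[planted_signatures[[t]], cols] <-
      expr[planted_signatures[[t]], cols] + config$signature_log2_shift
  }

  # planted module correlations: overwrite each target with the
  # shared-latent-factor construction around its population mean (empirical
  # centering would inflate the variance of group means and bias null tests)
  for (t in tumors) {
    mods <- planted_modules[[t]]
    for (i in seq_len(nrow(mods))) {
      tf <- mods$tf[i]; tg <- mods$target[i]
      for (g in groups) {
        cols <- which(group_of_sample == g)
        a <- if (g == t) config$r_in else config$r_out
        z_tf <- expr[tf, cols] - mu_group[tf, g]  # population sd is 1
        noise <- stats::rnorm(length(cols))
        center <- mu_group[tg, g] +
          if (g == t) config$signature_log2_shift else 0
        expr[tg, cols] <- center + a * z_tf + sqrt(1 - a^2) * noise
      }
    }
  }
  expr <- pmax(expr, 0)

  # planted masters and prognostic modules (tables realized by later
  # stages); the pan-cancer pool is smaller than the tumor count so some
  # pan masters are shared ("common" regulators spanning >= 2 tumors)
  pool_size <- min(max(1L, ceiling(config$n_tumor_types / 2)),
                   length(other_genes))
  pan_pool <- other_genes[seq_len(pool_size)]
  planted_masters <- lapply(seq_along(tumors), function(i) {
    t <- tumors[i]
    specific <- other_genes[pool_size + i]
    pan <- pan_pool[(i - 1L) %% length(pan_pool) + 1L]
    data.frame(gene = c(specific, pan),
               driver_class = c("tumor-specific", "pan-cancer"),
               stringsAsFactors = FALSE)
  })
  names(planted_masters) <- tumors

  # master regulators are over-expressed in their owning tumors, so shared
  # masters make cluster members separable by regulator expression
  for (t in tumors) {
    cols <- which(group_of_sample == t)
    mg <- planted_masters[[t]]$gene
    mg <- mg[!is.na(mg)]
    expr[mg, cols] <- expr[mg, cols] + config$signature_log2_shift
  }

  planted_prognostic <- lapply(tumors, function(t) {
    mods <- planted_modules[[t]]
    k <- min(2L, nrow(mods))
    data.frame(tf = mods$tf[seq_len(k)], target = mods$target[seq_len(k)],
               direction = c("noxious", "favorable")[seq_len(k)],
               stringsAsFactors = FALSE)
  })
  names(planted_prognostic) <- tumors

  truth <- list(
    planted_signatures = planted_signatures,
    planted_modules = planted_modules,
    planted_masters = planted_masters,
    planted_prognostic = planted_prognostic,
    tumors = tumors,
    matrisome_genes = mat_genes,
    tf_genes = tf_genes,
    other_genes = other_genes,
    config_seed = config$seed
  )

  list(expr = expr, annotation = annotation, matrisome = matrisome,
       truth = truth)
}

prior_sources <- function() {
  c("sourceA", "sourceB", "sourceC", "sourceD",
    "fantom_presence", "tfbs_enrichment")
}

#' Generate TF-target prior interactions with decoys
#'
#' Emulates the four textual TF-target databases plus a FANTOM5-like
#' TF-presence table and a TF-binding-site enrichment table. Every planted
#' module is guaranteed membership in at least two sources, one of which is
#' `fantom_presence` or `tfbs_enrichment`, so the downstream mining rule can
#' succeed with probability 1; on top of that, each source independently
#' lists each planted module with probability `prior_coverage`. Exactly
#' `decoy_rate` false (non-planted) TF-target pairs per true pair are added
#' with random source membership; about half the decoy targets are drawn
#' from planted signature genes so decoys genuinely compete downstream.
#'
#' @param config the [sim_config()] used for the cohort.
#' @param truth the ground truth from [generate_cohort()].
#' @return data.frame with columns `tf`, `target`, `source`; one row per
#'   (tf, target, source) triple, triples unique.
#' @export
generate_priors <- function(config, truth) {
  validate_sim_config(config)
  if (!identical(truth$config_seed, config$seed)) {
    stop("truth/config mismatch: ground truth was generated under seed ",
         truth$config_seed, ", config has seed ", config$seed)
  }
  set.seed(stage_seed(config, "priors"))
  sources <- prior_sources()

  planted <- do.call(rbind, truth$planted_modules)
  planted <- unique(planted[, c("tf", "target")])

  rows <- vector("list", nrow(planted))
  for (i in seq_len(nrow(planted))) {
    member <- stats::runif(6) < config$prior_coverage
    names(member) <- sources
    if (!member[["fantom_presence"]] && !member[["tfbs_enrichment"]]) {
      member[["fantom_presence"]] <- TRUE
    }
    if (sum(member) < 2) {
      member[[if (!member[["sourceA"]]) "sourceA" else "sourceB"]] <- TRUE
    }
    rows[[i]] <- data.frame(tf = planted$tf[i], target = planted$target[i],
                            source = sources[member], stringsAsFactors = FALSE)
  }

  # decoy pairs: exactly decoy_rate per true pair, never planted, unique
  n_decoy <- config$decoy_rate * nrow(planted)
  sig_genes <- unlist(truth$planted_signatures, use.names = FALSE)
  planted_key <- paste(planted$tf, planted$target)
  decoys <- data.frame(tf = character(), target = character(),
                       stringsAsFactors = FALSE)
  while (nrow(decoys) < n_decoy) {
    need <- n_decoy - nrow(decoys)
    tf <- sample(truth$tf_genes, need, replace = TRUE)
    from_sig <- stats::runif(need) < 0.5
    target <- ifelse(from_sig,
                     sample(sig_genes, need, replace = TRUE),
                     sample(truth$matrisome_genes, need, replace = TRUE))
    cand <- data.frame(tf = tf, target = target, stringsAsFactors = FALSE)
    cand <- cand[!paste(cand$tf, cand$target) %in% planted_key, , drop = FALSE]
    decoys <- unique(rbind(decoys, cand))
  }
  decoys <- decoys[seq_len(n_decoy), , drop = FALSE]
  decoy_rows <- lapply(seq_len(nrow(decoys)), function(i) {
    k <- sample(1:3, 1)
    data.frame(tf = decoys$tf[i], target = decoys$target[i],
               source = sample(sources, k), stringsAsFactors = FALSE)
  })

  out <- do.call(rbind, c(rows, decoy_rows))
  rownames(out) <- NULL
  out
}

#' Generate the driver table and PPI network honoring planted masters
#'
#' Planted tumor-specific masters receive mutation frequency
#' `driver_freq_specific` in their tumor; planted pan-cancer masters receive
#' a frequency in their owning tumor strictly above their own cross-cohort
#' mean. Each planted master is wired by PPI edges to half of its tumor's
#' planted-module TFs (well above the 10% coverage rule). Decoy drivers are
#' added that fail at least one filter: a tumor-specific decoy at frequency
#' 0.04, a flat-frequency pan-cancer decoy (never above its own mean), and a
#' frequency-passing decoy with no PPI edges. Background PPI edges among
#' unrelated genes are added for realism.
#'
#' @param config the [sim_config()].
#' @param truth ground truth from [generate_cohort()].
#' @return list with `drivers` (data.frame `gene`, `tumor_type`,
#'   `mutation_frequency`, `driver_class`) and `ppi` (data.frame
#'   `protein_a`, `protein_b`, `evidence`; undirected, deduplicated, no
#'   self-loops).
#' @export
generate_driver_ppi <- function(config, truth) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "driver_ppi"))
  tumors <- truth$tumors
  n_other <- length(truth$other_genes)

  drivers <- list()
  ppi <- list()
  evidences <- c("affinity-capture western", "reconstituted complex",
                 "two-hybrid", "biochemical activity")

  # pan-cancer masters may own several tumors ("common" regulators); emit
  # one frequency table per unique gene, high in every owning tumor
  pan_genes <- unique(unlist(lapply(truth$planted_masters, function(m)
    m$gene[m$driver_class == "pan-cancer"])))
  owners <- lapply(pan_genes, function(g)
    names(Filter(function(m) g %in% m$gene, truth$planted_masters)))
  names(owners) <- pan_genes
  for (g in pan_genes) {
    drivers[[length(drivers) + 1L]] <- data.frame(
      gene = g, tumor_type = tumors,
      mutation_frequency = ifelse(tumors %in% owners[[g]], 0.30, 0.08),
      driver_class = "pan-cancer", stringsAsFactors = FALSE)
  }

  # decoy driver genes start after the pan pool and the per-tumor specifics
  pool_size <- min(max(1L, ceiling(config$n_tumor_types / 2)), n_other)
  decoy_start <- pool_size + length(tumors)
  for (i in seq_along(tumors)) {
    t <- tumors[i]
    masters <- truth$planted_masters[[t]]
    spec <- masters$gene[masters$driver_class == "tumor-specific"]

    drivers[[length(drivers) + 1L]] <- data.frame(
      gene = spec, tumor_type = t,
      mutation_frequency = config$driver_freq_specific,
      driver_class = "tumor-specific", stringsAsFactors = FALSE)

    # PPI: planted masters contact half of the tumor's planted TFs
    tfs <- sort(unique(truth$planted_modules[[t]]$tf))
    n_link <- max(ceiling(length(tfs) / 2), 1L)
    for (m in masters$gene) {
      partners <- tfs[seq_len(n_link)]
      ppi[[length(ppi) + 1L]] <- data.frame(
        protein_a = m, protein_b = partners,
        evidence = sample(evidences, n_link, replace = TRUE),
        stringsAsFactors = FALSE)
    }

    # decoys: frequency failure, mean failure, coverage failure
    dg <- truth$other_genes[decoy_start + (i - 1L) * 3L + 1:3]
    dg <- dg[!is.na(dg)]
    if (length(dg) >= 1L) {
      drivers[[length(drivers) + 1L]] <- data.frame(
        gene = dg[1L], tumor_type = t, mutation_frequency = 0.04,
        driver_class = "tumor-specific", stringsAsFactors = FALSE)
    }
    if (length(dg) >= 2L) {
      drivers[[length(drivers) + 1L]] <- data.frame(
        gene = dg[2L], tumor_type = tumors, mutation_frequency = 0.10,
        driver_class = "pan-cancer", stringsAsFactors = FALSE)
    }
    if (length(dg) >= 3L) {
      # passes the frequency filter, but gets no PPI edge
      drivers[[length(drivers) + 1L]] <- data.frame(
        gene = dg[3L], tumor_type = t, mutation_frequency = 0.20,
        driver_class = "tumor-specific", stringsAsFactors = FALSE)
    }
  }

  # background PPI noise among non-driver, non-TF genes
  bg <- truth$matrisome_genes
  if (length(bg) >= 4L) {
    n_bg <- 50L
    a <- sample(bg, n_bg, replace = TRUE)
    b <- sample(bg, n_bg, replace = TRUE)
    keep <- a != b
    ppi[[length(ppi) + 1L]] <- data.frame(
      protein_a = a[keep], protein_b = b[keep],
      evidence = sample(evidences, sum(keep), replace = TRUE),
      stringsAsFactors = FALSE)
  }

  drivers <- do.call(rbind, drivers)
  rownames(drivers) <- NULL
  ppi <- do.call(rbind, ppi)
  # deduplicate as unordered pairs, drop self-loops
  lo <- pmin(ppi$protein_a, ppi$protein_b)
  hi <- pmax(ppi$protein_a, ppi$protein_b)
  keep <- !duplicated(paste(lo, hi)) & lo != hi
  ppi <- data.frame(protein_a = lo[keep], protein_b = hi[keep],
                    evidence = ppi$evidence[keep], stringsAsFactors = FALSE)
  list(drivers = drivers, ppi = ppi)
}

#' Generate survival times honoring planted prognostic modules
#'
#' Survival is exponential with a per-sample hazard. Samples in a tumor with
#' a planted prognostic module have their hazard multiplied by
#' `hazard_ratio_prognostic` when they sit on the risk side of the module's
#' mean-dichotomized activity (above the mean for a noxious module, below it
#' for a favorable one). Censoring is independent: each sample is censored
#' with probability `censoring_rate`, in which case the recorded time is
#' uniform on (0, true time).
#'
#' @param config the [sim_config()].
#' @param truth ground truth from [generate_cohort()].
#' @param expr expression matrix from the same cohort.
#' @param annotation annotation from the same cohort.
#' @param baseline_hazard events per day for an unaffected sample.
#' @return the annotation with `survival_days` and `event` filled.
#' @export
generate_survival <- function(config, truth, expr, annotation,
                              baseline_hazard = 1 / 1000) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "survival"))
  hazard <- rep(baseline_hazard, nrow(annotation))
  names(hazard) <- annotation$sample_id
  hr <- config$hazard_ratio_prognostic

  for (t in truth$tumors) {
    prog <- truth$planted_prognostic[[t]]
    cols <- annotation$sample_id[annotation$tumor_type == t &
                                   annotation$sample_class != "healthy"]
    if (length(cols) == 0L || is.null(prog) || nrow(prog) == 0L) next
    for (i in seq_len(nrow(prog))) {
      act <- colMeans(expr[c(prog$tf[i], prog$target[i]), cols, drop = FALSE])
      high <- act > mean(act)
      at_risk <- if (prog$direction[i] == "noxious") high else !high
      hazard[cols][at_risk] <- hazard[cols][at_risk] * hr
    }
  }

  true_time <- stats::rexp(nrow(annotation), rate = hazard)
  censored <- stats::runif(nrow(annotation)) < config$censoring_rate
  obs <- ifelse(censored, stats::runif(nrow(annotation)) * true_time, true_time)
  annotation$survival_days <- obs
  annotation$event <- as.integer(!censored)
  annotation
}

#' Generate immunohistochemistry staining and drug-gene interaction tables
#'
#' Staining levels are drawn per (protein, sample) with configurable High and
#' Medium probabilities for every planted-module TF and target. The drug
#' table covers a configurable fraction of the planted matrisome signature
#' genes, module TFs and master regulators, with FDA-approval and
#' tumor-label annotations; rows with an empty mechanism can be generated at
#' a configurable rate to exercise the load-time filter
#' ([load_drug_interactions()]).
#'
#' @param config the [sim_config()].
#' @param truth ground truth from [generate_cohort()].
#' @param p_high,p_medium probabilities of High and Medium staining.
#' @param samples_per_protein assayed samples per protein.
#' @param drug_coverage fraction of each layer's genes receiving a drug row.
#' @param empty_mechanism_rate fraction of drug rows emitted with an empty
#'   mechanism (these must be removed at load).
#' @return list with `staining` (data.frame `protein`, `sample_id`, `level`)
#'   and `drugs` (data.frame `drug`, `gene`, `mechanism`,
#'   `fda_approved_cancer_drug`, `approved_tumor_types`).
#' @export
generate_staining_drugs <- function(config, truth,
                                    p_high = 0.3, p_medium = 0.3,
                                    samples_per_protein = 12L,
                                    drug_coverage = 0.6,
                                    empty_mechanism_rate = 0) {
  validate_sim_config(config)
  stopifnot(p_high >= 0, p_medium >= 0, p_high + p_medium <= 1)
  set.seed(stage_seed(config, "staining_drugs"))

  mods <- do.call(rbind, truth$planted_modules)
  proteins <- sort(unique(c(mods$tf, mods$target)))
  levels <- c("High", "Medium", "Low", "Not detected")
  p_rest <- (1 - p_high - p_medium) / 2
  staining <- do.call(rbind, lapply(proteins, function(p) {
    data.frame(protein = p,
               sample_id = sprintf("IHC%03d", seq_len(samples_per_protein)),
               level = sample(levels, samples_per_protein, replace = TRUE,
                              prob = c(p_high, p_medium, p_rest, p_rest)),
               stringsAsFactors = FALSE)
  }))

  layer_genes <- list(
    matrisome = sort(unique(unlist(truth$planted_signatures))),
    TF = sort(unique(mods$tf)),
    master = sort(unique(unlist(lapply(truth$planted_masters,
                                       function(m) m$gene))))
  )
  mechanisms <- c("inhibitor", "antibody", "antagonist", "chelator")
  drugs <- list()
  for (layer in names(layer_genes)) {
    gs <- layer_genes[[layer]]
    covered <- gs[stats::runif(length(gs)) < drug_coverage]
    for (g in covered) {
      fda <- stats::runif(1) < 0.5
      approved <- if (fda) {
        paste(sort(sample(truth$tumors, sample(0:2, 1))), collapse = ",")
      } else ""
      mech <- if (stats::runif(1) < empty_mechanism_rate) "" else
        sample(mechanisms, 1)
      drugs[[length(drugs) + 1L]] <- data.frame(
        drug = paste0("drug_", g), gene = g, mechanism = mech,
        fda_approved_cancer_drug = fda, approved_tumor_types = approved,
        stringsAsFactors = FALSE)
    }
  }
  drugs <- if (length(drugs)) do.call(rbind, drugs) else
    data.frame(drug = character(), gene = character(), mechanism = character(),
               fda_approved_cancer_drug = logical(),
               approved_tumor_types = character(), stringsAsFactors = FALSE)
  rownames(drugs) <- NULL
  list(staining = staining, drugs = drugs)
}

#' Load a drug-gene interaction table, dropping mechanism-less entries
#'
#' Rows with an empty or missing mechanism never enter the pipeline.
#'
#' @param drugs data.frame as produced by [generate_staining_drugs()], or a
#'   path to a headered TSV with the same columns.
#' @return filtered data.frame.
#' @export
load_drug_interactions <- function(drugs) {
  if (is.character(drugs)) {
    drugs <- utils::read.delim(drugs, stringsAsFactors = FALSE)
  }
  drugs[!is.na(drugs$mechanism) & nzchar(drugs$mechanism), , drop = FALSE]
}

#' Generate the complete synthetic study in one call
#'
#' Runs every generator stage under its own substream of `config$seed` and
#' returns all tables plus the ground truth.
#'
#' @param config a [sim_config()].
#' @param ... passed to [generate_staining_drugs()].
#' @return list with `expr`, `annotation`, `matrisome`, `priors`, `drivers`,
#'   `ppi`, `staining`, `drugs`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), ...) {
  cohort <- generate_cohort(config)
  priors <- generate_priors(config, cohort$truth)
  dp <- generate_driver_ppi(config, cohort$truth)
  annotation <- generate_survival(config, cohort$truth, cohort$expr,
                                  cohort$annotation)
  sd <- generate_staining_drugs(config, cohort$truth, ...)
  list(expr = cohort$expr, annotation = annotation,
       matrisome = cohort$matrisome, priors = priors,
       drivers = dp$drivers, ppi = dp$ppi,
       staining = sd$staining, drugs = sd$drugs,
       truth = cohort$truth)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Expression as a gene x sample TSV; annotation, priors, drivers, PPI,
#' staining and drugs as headered TSVs; the matrisome catalog as a
#' two-column TSV; the ground truth as a JSON sidecar.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  expr_df <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  w(expr_df, "expression.tsv")
  w(sim$annotation, "annotation.tsv")
  w(sim$matrisome, "matrisome.tsv")
  w(sim$priors, "priors.tsv")
  w(sim$drivers, "drivers.tsv")
  w(sim$ppi, "ppi.tsv")
  w(sim$staining, "staining.tsv")
  w(sim$drugs, "drugs.tsv")
  truth <- sim$truth
  truth$planted_modules <- lapply(truth$planted_modules, as.list)
  truth$planted_masters <- lapply(truth$planted_masters, as.list)
  truth$planted_prognostic <- lapply(truth$planted_prognostic, as.list)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
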