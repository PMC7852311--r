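test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(sim_config(r_in = 0.2, r_out = 0.5), "r_out")
  expect_error(sim_config(n_matrisome = 500, n_genes = 300), "n_matrisome")
  expect_error(sim_config(n_tfs = 200, n_genes = 300, n_matrisome = 120),
               "n_tfs")
  expect_error(sim_config(prior_coverage = 1.2), "prior_coverage")
  expect_error(sim_config(samples_per_tumor = 0), "samples_per_tumor")
  expect_error(sim_config(hazard_ratio_prognostic = 0), "hazard_ratio")
  expect_error(sim_config(planted_modules_per_tumor = 9,
                          signature_genes_per_tumor = 8),
               "planted_modules_per_tumor")
})

test_that("generation is deterministic: same config and seed, identical output", {
  a <- simulate_study(small_config(seed = 42))
  b <- simulate_study(small_config(seed = 42))
  expect_identical(a$expr, b$expr)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$priors, b$priors)
  expect_identical(a$drivers, b$drivers)
  expect_identical(a$ppi, b$ppi)
  expect_identical(a$truth, b$truth)
  d <- simulate_study(small_config(seed = 43))
  expect_false(identical(a$expr, d$expr))
})

test_that("expression matrix is well-formed: non-negative, complete, consistent", {
  sim <- small_sim()
  expect_false(anyNA(sim$expr))
  expect_true(all(sim$expr >= 0))
  expect_identical(colnames(sim$expr), sim$annotation$sample_id)
  expect_setequal(sim$matrisome$gene_id,
                  grep("^MAT", rownames(sim$expr), value = TRUE))
  # every sample has exactly one annotation row
  expect_false(any(duplicated(sim$annotation$sample_id)))
  # planted identifiers all exist
  tr <- sim$truth
  expect_true(all(unlist(tr$planted_signatures) %in% rownames(sim$expr)))
  mods <- do.call(rbind, tr$planted_modules)
  expect_true(all(c(mods$tf, mods$target) %in% rownames(sim$expr)))
})

test_that("planted pairs hit the requested in-tumor correlation", {
  co <- generate_cohort(small_config(seed = 5, samples_per_tumor = 200))
  ann <- co$annotation
  for (t in co$truth$tumors) {
    ids <- ann$sample_id[ann$tumor_type == t & ann$sample_class != "healthy"]
    m <- co$truth$planted_modules[[t]]
    r <- vapply(seq_len(nrow(m)), function(i)
      cor(co$expr[m$tf[i], ids], co$expr[m$target[i], ids]), numeric(1))
    expect_true(all(abs(r - 0.8) < 0.1))
  }
  # calibration tightens with sample size: mean absolute deviation < 0.05
  co <- generate_cohort(small_config(seed = 6, samples_per_tumor = 500,
                                     n_tumor_types = 2))
  ann <- co$annotation
  devs <- unlist(lapply(co$truth$tumors, function(t) {
    ids <- ann$sample_id[ann$tumor_type == t & ann$sample_class != "healthy"]
    m <- co$truth$planted_modules[[t]]
    abs(vapply(seq_len(nrow(m)), function(i)
      cor(co$expr[m$tf[i], ids], co$expr[m$target[i], ids]), numeric(1)) - 0.8)
  }))
  expect_lt(mean(devs), 0.05)
})

test_that("with zero signature shift, tumor vs healthy differs only by sampling noise", {
  p_all <- c()
  for (s in 1:5) {
    co <- generate_cohort(small_config(seed = s, signature_log2_shift = 0))
    ann <- co$annotation
    t <- co$truth$tumors[1]
    tu <- ann$sample_id[ann$tumor_type == t & ann$sample_class != "healthy"]
    hl <- ann$sample_id[ann$tumor_type == t & ann$sample_class == "healthy"]
    p <- apply(co$expr[co$matrisome$gene_id, ], 1, function(v)
      t.test(v[tu], v[hl])$p.value)
    p_all <- c(p_all, p)
  }
  expect_gt(mean(p_all < 0.05), 0.01)
  expect_lt(mean(p_all < 0.05), 0.10)
})

test_that("prior generation honors coverage and decoy-rate contracts", {
  cfg <- small_config(seed = 9)
  co <- generate_cohort(cfg)
  planted <- unique(do.call(rbind, co$truth$planted_modules)[, c("tf", "target")])
  pk <- paste(planted$tf, planted$target)

  # decoy_rate = 0: every emitted pair is planted
  cfg0 <- small_config(seed = 9, decoy_rate = 0)
  pr0 <- generate_priors(cfg0, generate_cohort(cfg0)$truth)
  expect_true(all(paste(pr0$tf, pr0$target) %in% pk))

  # prior_coverage = 1: every planted module is in all six sources
  cfg1 <- small_config(seed = 9, prior_coverage = 1, decoy_rate = 0)
  pr1 <- generate_priors(cfg1, generate_cohort(cfg1)$truth)
  n_src <- table(paste(pr1$tf, pr1$target))
  expect_true(all(n_src == 6L))

  # decoy_rate = 3: non-planted pair count is exactly 3x the planted count
  pr3 <- generate_priors(cfg, co$truth)
  pairs <- unique(pr3[, c("tf", "target")])
  is_planted <- paste(pairs$tf, pairs$target) %in% pk
  expect_identical(sum(!is_planted), 3L * nrow(planted))
  expect_identical(sum(is_planted), nrow(planted))

  # mining rule satisfiable for every planted pair: >= 2 sources, one FANTOM5-like
  src <- split(pr3$source, paste(pr3$tf, pr3$target))
  for (k in pk) {
    expect_gte(length(src[[k]]), 2L)
    expect_true(any(src[[k]] %in% c("fantom_presence", "tfbs_enrichment")))
  }

  # truth/config mismatch is refused
  expect_error(generate_priors(small_config(seed = 10), co$truth), "mismatch")
})

test_that("planted masters pass both filters by construction; decoys fail", {
  sim <- small_sim()
  drv <- sim$drivers
  for (t in sim$truth$tumors) {
    masters <- sim$truth$planted_masters[[t]]
    spec <- masters$gene[masters$driver_class == "tumor-specific"]
    f <- drv$mutation_frequency[drv$gene == spec & drv$tumor_type == t]
    expect_gt(f, 0.05)
    pan <- masters$gene[masters$driver_class == "pan-cancer"]
    rows <- drv[drv$gene == pan & drv$driver_class == "pan-cancer", ]
    expect_gt(rows$mutation_frequency[rows$tumor_type == t],
              mean(rows$mutation_frequency))
    # PPI wiring covers > 10% of the tumor's planted TFs
    tfs <- unique(sim$truth$planted_modules[[t]]$tf)
    for (m in masters$gene) {
      partners <- unique(c(sim$ppi$protein_b[sim$ppi$protein_a == m],
                           sim$ppi$protein_a[sim$ppi$protein_b == m]))
      expect_gt(length(intersect(partners, tfs)) / length(tfs), 0.10)
    }
  }
  # a 4%-frequency decoy exists and fails the frequency filter
  expect_true(any(drv$mutation_frequency == 0.04 &
                    drv$driver_class == "tumor-specific"))
  # PPI is deduplicated and loop-free
  expect_true(all(sim$ppi$protein_a != sim$ppi$protein_b))
  expect_false(any(duplicated(paste(sim$ppi$protein_a, sim$ppi$protein_b))))
})

test_that("survival generation respects censoring and fills every sample", {
  cfg <- small_config(seed = 13, censoring_rate = 0)
  co <- generate_cohort(cfg)
  ann <- generate_survival(cfg, co$truth, co$expr, co$annotation)
  expect_true(all(ann$event == 1L))
  expect_true(all(ann$survival_days > 0))
  cfg2 <- small_config(seed = 13, censoring_rate = 0.5)
  ann2 <- generate_survival(cfg2, co$truth, co$expr, co$annotation)
  expect_gt(mean(ann2$event == 0L), 0.4)
  expect_lt(mean(ann2$event == 0L), 0.6)
})

test_that("staining and drug generation expose their configurable contracts", {
  cfg <- small_config(seed = 17)
  truth <- generate_cohort(cfg)$truth
  # all-High staining: PPS = 100 downstream for every protein
  sd1 <- generate_staining_drugs(cfg, truth, p_high = 1, p_medium = 0)
  mods <- do.call(rbind, truth$planted_modules)
  pps <- staining_crossval(mods, sd1$staining)
  expect_true(all(pps$pps == 100))
  # zero drug coverage: empty table, empty downstream report
  sd0 <- generate_staining_drugs(cfg, truth, drug_coverage = 0)
  expect_identical(nrow(sd0$drugs), 0L)
  rep0 <- map_druggability(list(matrisome = "MAT001", tfs = "TF001",
                                masters = "OTH001"),
                           load_drug_interactions(sd0$drugs), "T01")
  expect_identical(nrow(rep0), 0L)
  # empty-mechanism rows are exactly the ones removed at load
  sdm <- generate_staining_drugs(cfg, truth, drug_coverage = 1,
                                 empty_mechanism_rate = 0.2)
  loaded <- load_drug_interactions(sdm$drugs)
  expect_identical(nrow(loaded), sum(nzchar(sdm$drugs$mechanism)))
  expect_true(all(nzchar(loaded$mechanism)))
})

test_that("a written simulation round-trips through plain-text files", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression.tsv", "annotation.tsv", "matrisome.tsv", "priors.tsv",
    "drivers.tsv", "ppi.tsv", "staining.tsv", "drugs.tsv",
    "ground_truth.json")))))
  expr2 <- utils::read.delim(file.path(dir, "expression.tsv"),
                             check.names = FALSE)
  expect_identical(expr2$gene_id, rownames(sim$expr))
  expect_equal(as.matrix(expr2[, -1]), sim$expr, ignore_attr = TRUE,
               tolerance = 1e-8)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(unlist(gt$planted_signatures$T01),
                  sim$truth$planted_signatures$T01)
})
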