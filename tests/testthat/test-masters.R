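test_that("driver frequency filters are strict at their boundaries", {
  drivers <- data.frame(
    gene = c("S6", "S5", "P1", "P1", "P2", "P2"),
    tumor_type = c("TA", "TA", "TA", "TB", "TA", "TB"),
    mutation_frequency = c(0.06, 0.05, 0.10, 0.06, 0.08, 0.08),
    driver_class = c("tumor-specific", "tumor-specific",
                     "pan-cancer", "pan-cancer", "pan-cancer", "pan-cancer"),
    stringsAsFactors = FALSE)
  out <- filter_drivers(drivers, "TA")
  expect_true("S6" %in% out$gene)    # 6% > 5%
  expect_false("S5" %in% out$gene)   # exactly 5%: strict >
  expect_true("P1" %in% out$gene)    # 0.10 > mean(0.10, 0.06) = 0.08
  expect_false("P2" %in% out$gene)   # exactly at its own mean: strict >
  # a pan driver with no frequency for the tumor is skipped with a warning
  drivers2 <- rbind(drivers, data.frame(
    gene = "P3", tumor_type = "TB", mutation_frequency = 0.5,
    driver_class = "pan-cancer", stringsAsFactors = FALSE))
  expect_warning(out2 <- filter_drivers(drivers2, "TA"), "P3")
  expect_false("P3" %in% out2$gene)
})

test_that("PPI coverage rule is strict at 10% and computes coverage exactly", {
  tfs <- sprintf("TF%02d", 1:20)
  cand <- data.frame(gene = c("D3", "D2"), driver_class = "tumor-specific",
                     frequency = 0.2, stringsAsFactors = FALSE)
  ppi <- data.frame(
    protein_a = c(rep("D3", 3), rep("D2", 2)),
    protein_b = c(tfs[1:3], tfs[1:2]),
    evidence = "two-hybrid", stringsAsFactors = FALSE)
  out <- link_masters(cand, ppi, tfs, "TA")
  expect_identical(out$driver, "D3")          # 3/20 = 15% > 10%
  expect_equal(out$coverage, 0.15)            # D2: 2/20 = 10% exactly, dropped
  expect_identical(out$tf_partners, "TF01,TF02,TF03")
  # undirected edges count regardless of column order
  ppi_rev <- ppi
  names(ppi_rev)[1:2] <- c("protein_b", "protein_a")
  out_rev <- link_masters(cand, ppi_rev[, c("protein_a", "protein_b",
                                            "evidence")], tfs, "TA")
  expect_identical(out_rev$driver, "D3")
  expect_warning(none <- link_masters(cand, ppi[0, ], tfs), "empty PPI")
  expect_identical(nrow(none), 0L)
  expect_error(link_masters(cand, ppi, character()), "non-empty")
})

test_that("planted masters are recovered exactly from the generated study", {
  sim <- small_sim()
  pipe <- small_pipeline()
  fin <- pipe$modules[pipe$modules$final, ]
  masters <- lapply(sim$truth$tumors, function(t)
    link_masters(filter_drivers(sim$drivers, t), sim$ppi,
                 unique(fin$tf[fin$tumor == t]), t))
  names(masters) <- sim$truth$tumors
  for (t in sim$truth$tumors) {
    expect_setequal(masters[[t]]$driver, sim$truth$planted_masters[[t]]$gene)
  }
  # summary arithmetic
  s <- regulator_summary(masters)
  expect_equal(s$avg_total, mean(vapply(masters, nrow, integer(1))))
  n_links <- sum(vapply(masters, function(m)
    sum(lengths(strsplit(m$tf_partners, ","))), numeric(1)))
  expect_equal(s$tf_per_master, n_links / sum(vapply(masters, nrow, integer(1))))
  # pan masters shared by >= 2 tumors are "common"
  occ <- table(unlist(lapply(masters, function(m) unique(m$driver))))
  expect_setequal(s$common, names(occ)[occ >= 2])
})

test_that("regulator summary handles tumors without masters", {
  empty <- data.frame(driver = character(), tumor = character(),
                      driver_class = character(), coverage = numeric(),
                      tf_partners = character(), stringsAsFactors = FALSE)
  s <- regulator_summary(list(TA = empty))
  expect_equal(s$avg_total, 0)
  expect_identical(s$common, character())
  # weighted average of TF partners: masters with 3 and 5 partners -> 4
  m <- data.frame(driver = c("D1", "D2"), tumor = "TA",
                  driver_class = "pan-cancer", coverage = 0.5,
                  tf_partners = c("a,b,c", "d,e,f,g,h"),
                  stringsAsFactors = FALSE)
  expect_equal(regulator_summary(list(TA = m))$tf_per_master, 4)
})

test_that("cluster-level regulator selection separates planted clusters", {
  sim <- small_sim()
  pipe <- small_pipeline()
  fin <- pipe$modules[pipe$modules$final, ]
  masters <- lapply(sim$truth$tumors, function(t)
    link_masters(filter_drivers(sim$drivers, t), sim$ppi,
                 unique(fin$tf[fin$tumor == t]), t))
  names(masters) <- sim$truth$tumors
  # tumors sharing a pan-cancer master form the separable "cluster"
  occ <- table(unlist(lapply(masters, function(m) unique(m$driver))))
  shared_gene <- names(occ)[occ >= 2][1]
  members <- names(Filter(function(m) shared_gene %in% m$driver, masters))
  sel <- cluster_regulator_selection(masters, sim$expr, sim$annotation,
                                     members, seed = 5)
  expect_gt(sel$auc, 0.9)
  expect_equal(sum(sel$importance), 1)
  # single shared regulator: importance collapses to 1
  if (length(sel$regulators) == 1L) {
    expect_equal(unname(sel$importance), 1)
  }
  # permuted labels: chance-level AUC
  ann_perm <- sim$annotation
  tum <- ann_perm$sample_class != "healthy"
  set.seed(6)
  ann_perm$tumor_type[tum] <- sample(ann_perm$tumor_type[tum])
  sel_perm <- cluster_regulator_selection(masters, sim$expr, ann_perm,
                                          members, seed = 5)
  expect_lt(abs(sel_perm$auc - 0.5), 0.12)
  # empty intersection: warning and empty result
  m2 <- masters
  m2[[members[1]]] <- m2[[members[1]]][0, ]
  expect_warning(out <- cluster_regulator_selection(m2, sim$expr,
                                                    sim$annotation, members),
                 "no shared")
  expect_length(out$regulators, 0)
})

test_that("pathway over-representation matches the hypergeometric closed form", {
  universe <- sprintf("g%04d", 1:1000)
  pw <- list(hit = universe[1:10], miss = universe[901:1000])
  query <- universe[1:10]  # exactly the "hit" pathway
  res <- pathway_enrichment(query, pw, universe)
  hit <- res[res$pathway == "hit", ]
  expect_equal(hit$p_value, 1 / choose(1000, 10))
  expect_identical(res$pathway[1], "hit")  # minimal P among pathways
  # disjoint pathway: P = 1
  expect_equal(res$p_value[res$pathway == "miss"], 1)
  # FDR is the BH adjustment of the P column
  expect_equal(sort(res$fdr), sort(p.adjust(res$p_value, "BH")))
  # mutational activation needs >= 2 cancer-specific masters in the pathway
  res1 <- pathway_enrichment(query, pw, universe,
                             specific_masters = universe[1])
  expect_false(res1$mutationally_activated[res1$pathway == "hit"])
  res2 <- pathway_enrichment(query, pw, universe,
                             specific_masters = universe[1:2])
  expect_true(res2$mutationally_activated[res2$pathway == "hit"])
  # query genes outside the universe are an error
  expect_error(pathway_enrichment(c(query, "alien"), pw, universe), "alien")
})

test_that("GMT files round-trip through read_gmt", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdesc\tg1\tg2\tg3", "pwB\tdesc\tg9"), path)
  gmt <- read_gmt(path)
  expect_identical(gmt, list(pwA = c("g1", "g2", "g3"), pwB = "g9"))
})
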