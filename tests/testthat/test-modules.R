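test_that("fisher_z matches the closed form and its symmetries", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  r <- seq(-0.99, 0.99, by = 0.03)
  # closed form to 12 significant digits
  expect_equal(fisher_z(r), 0.5 * log((1 + r) / (1 - r)), tolerance = 1e-12)
  # odd function
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("candidate mining enforces the two-source FANTOM5-obligatory rule", {
  sig <- list(tumor = "T01", genes = c("MAT001", "MAT002", "MAT003"))
  priors <- data.frame(
    tf = c("TF1", "TF1", "TF2", "TF2", "TF3", "TF4"),
    target = c("MAT001", "MAT001", "MAT002", "MAT002", "MAT003", "MAT009"),
    source = c("sourceA", "fantom_presence",   # kept: 2 sources, one FANTOM5
               "sourceA", "sourceB",           # dropped: no FANTOM5 evidence
               "fantom_presence",              # dropped: single scheme
               "fantom_presence"),             # dropped: target not in signature
    stringsAsFactors = FALSE)
  cand <- mine_candidates(priors, sig, "T01")
  expect_identical(cand$tf, "TF1")
  expect_identical(cand$target, "MAT001")
  expect_identical(cand$n_sources, 2L)
  # tfbs_enrichment also satisfies the obligatory slot
  priors2 <- data.frame(tf = "TF9", target = "MAT002",
                        source = c("sourceC", "tfbs_enrichment"),
                        stringsAsFactors = FALSE)
  expect_identical(nrow(mine_candidates(priors2, sig, "T01")), 1L)
  # empty signature: warning, empty result
  expect_warning(none <- mine_candidates(priors, list(genes = character()),
                                         "T01"), "empty signature")
  expect_identical(nrow(none), 0L)
})

test_that("correlation filter computes partitioned r and drops non-positive pairs", {
  set.seed(6)
  n <- 150
  z <- rnorm(n)
  expr_in <- rbind(TFp = z, MATp = 0.8 * z + 0.6 * rnorm(n),
                   TFn = z, MATn = -0.7 * z + rnorm(n))
  expr_rest <- matrix(rnorm(4 * n), nrow = 4)
  expr <- cbind(expr_in, expr_rest) + 6
  rownames(expr) <- c("TFp", "MATp", "TFn", "MATn")
  colnames(expr) <- sprintf("s%03d", 1:(2 * n))
  annot <- data.frame(sample_id = colnames(expr),
                      tumor_type = rep(c("TA", "TB"), each = n),
                      sample_class = "primary", stringsAsFactors = FALSE)
  cand <- data.frame(tf = c("TFp", "TFn"), target = c("MATp", "MATn"),
                     tumor = "TA", sources = "x", n_sources = 2L,
                     stringsAsFactors = FALSE)
  out <- correlation_filter(cand, expr, annot, "TA")
  # anti-correlated pair removed
  expect_identical(out$tf, "TFp")
  expect_equal(out$r_in, 0.8, tolerance = 0.1)
  expect_equal(out$zcor_in, atanh(out$r_in))
  expect_equal(out$zcor_rest, atanh(out$r_rest))
  # r_rest computed on the other tumor only: near zero here
  expect_lt(abs(out$r_rest), 0.2)
  # rest partition excludes the owning tumor entirely: make the pair
  # perfectly correlated in TA; r_rest must not move
  expr2 <- expr
  expr2["MATp", 1:n] <- expr2["TFp", 1:n]
  out2 <- correlation_filter(cand[1, ], expr2, annot, "TA")
  expect_equal(out2$r_rest, out$r_rest)
})

test_that("youden threshold matches exhaustive search and the worked example", {
  res <- youden_threshold(c(2, 3, 4), c(0, 0.5, 1))
  expect_equal(res$threshold, 1.5)
  expect_equal(res$j_statistic, 1)

  # oracle equivalence on random instances, including ties
  set.seed(9)
  for (i in 1:50) {
    zin <- round(rnorm(sample(3:50, 1), mean = 1), 2)
    zrest <- round(rnorm(sample(3:50, 1)), 2)
    got <- youden_threshold(zin, zrest)
    want <- brute_force_youden(zin, zrest)
    expect_identical(got$threshold, want$threshold)
    expect_identical(got$j_statistic, want$j_statistic)
  }

  # identically distributed values: J near zero in expectation
  set.seed(10)
  js <- replicate(100, youden_threshold(rnorm(40), rnorm(40))$j_statistic)
  expect_lt(mean(js), 0.35)

  # separation growing without bound drives J to 1
  expect_equal(youden_threshold(rnorm(50) + 100, rnorm(50))$j_statistic, 1)

  expect_error(youden_threshold(numeric(), 1), "non-empty")
  expect_error(youden_threshold(c(1, 1), c(1, 1)), "identical")
})

test_that("adaptive lasso keeps the true support and drops independent TFs", {
  n <- 300
  hits <- replicate(30, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 2 * x1 + rnorm(n)
    expr <- rbind(TF1 = x1, TF2 = x2, TGT = y)
    colnames(expr) <- sprintf("s%03d", 1:n)
    kept <- adaptive_lasso_prune(expr, "TGT", c("TF1", "TF2"))
    identical(kept, "TF1")
  })
  expect_gte(mean(hits), 0.95)

  # single TF input is returned unchanged
  expr <- matrix(rnorm(20), 2, dimnames = list(c("TF1", "TGT"), NULL))
  expect_identical(adaptive_lasso_prune(expr, "TGT", "TF1"), "TF1")

  # duplicated TF columns: exactly one kept, lexicographically first
  set.seed(12)
  x <- rnorm(n); y <- x + rnorm(n, sd = 0.5)
  expr2 <- rbind(TFb = x, TFa = x, TGT = y)
  colnames(expr2) <- sprintf("s%03d", 1:n)
  kept <- adaptive_lasso_prune(expr2, "TGT", c("TFb", "TFa"))
  expect_identical(kept, "TFa")
})

test_that("models 2 and 3 keep strong edges, reject null edges, stay within model 1", {
  set.seed(14)
  n <- 120
  z <- rnorm(n)
  expr <- rbind(TF1 = z, TF2 = rnorm(n),
                MATa = 0.8 * z + 0.6 * rnorm(n), MATb = rnorm(n))
  colnames(expr) <- sprintf("s%03d", 1:n)
  model1 <- data.frame(tf = c("TF1", "TF2"), target = c("MATa", "MATb"),
                       stringsAsFactors = FALSE)
  for (fun in list(model2_sparse_bayes, model3_mixed_graphical)) {
    out <- fun(expr, model1, seed = 21)
    key <- paste(out$tf, out$target)
    expect_true("TF1 MATa" %in% key)          # strong edge is stable
    expect_false("TF2 MATb" %in% key)         # null edge rejected
    expect_true(all(key %in% paste(model1$tf, model1$target)))  # subset
    # strong edge selected in >= 9/10 folds
    expect_gte(out$frequency[key == "TF1 MATa"], 0.9)
    # empty model 1 gives empty output
    empty <- model1[0, ]
    expect_identical(nrow(fun(expr, empty, seed = 1)), 0L)
    expect_error(fun(expr[, 1:10], model1), "20 samples")
  }
})

test_that("model 3 prunes the conditionally redundant parent", {
  set.seed(15)
  n <- 200
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n)             # shadow of TF1: no conditional signal
  y <- x1 + rnorm(n)
  expr <- rbind(TF1 = x1, TF2 = x2, TGT = y)
  colnames(expr) <- sprintf("s%03d", 1:n)
  model1 <- data.frame(tf = c("TF1", "TF2"), target = c("TGT", "TGT"),
                       stringsAsFactors = FALSE)
  freq <- c(TF1 = 0, TF2 = 0)
  for (s in 1:5) {
    out <- model3_mixed_graphical(expr, model1, seed = s, stability = 0)
    f <- setNames(rep(0, 2), c("TF1", "TF2"))
    f[out$tf] <- out$frequency
    freq <- freq + f
  }
  # the direct parent is selected strictly more often than its shadow
  expect_gt(freq[["TF1"]], freq[["TF2"]])
})

test_that("consensus keeps modules present in at least two models", {
  model1 <- data.frame(tf = c("A", "B", "C"), target = c("x", "y", "z"),
                       stringsAsFactors = FALSE)
  model2 <- data.frame(tf = "A", target = "x", stringsAsFactors = FALSE)
  model3 <- data.frame(tf = c("C", "Q"), target = c("z", "q"),
                       stringsAsFactors = FALSE)  # Q/q not in model 1
  out <- consensus_modules(model1, model2, model3)
  expect_identical(out$final, c(TRUE, FALSE, TRUE))
  # a pair only in models 2/3 never appears (restriction contract)
  expect_false("Q" %in% out$tf)
  # present in all three: kept
  out2 <- consensus_modules(model1, model1, model1)
  expect_true(all(out2$final))
})

test_that("staining cross-validation computes PPS and distinguishes not-assayed", {
  staining <- data.frame(
    protein = c(rep("P1", 3), rep("P2", 4)),
    sample_id = c(sprintf("s%d", 1:3), sprintf("s%d", 1:4)),
    level = c("High", "Medium", "Low",
              rep("Not detected", 4)),
    stringsAsFactors = FALSE)
  modules <- data.frame(tf = c("P1", "P3"), target = c("P2", "P2"),
                        stringsAsFactors = FALSE)
  out <- staining_crossval(modules, staining)
  p1 <- out[out$protein == "P1", ]
  expect_equal(round(p1$pps, 1), 66.7)
  expect_true(p1$validated)
  p2 <- out[out$protein == "P2", ]
  expect_equal(p2$pps, 0)
  expect_false(p2$validated)
  p3 <- out[out$protein == "P3", ]
  expect_false(p3$assayed)
  expect_true(is.na(p3$pps))
})
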