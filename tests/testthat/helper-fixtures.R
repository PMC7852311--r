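# Shared fixtures: a reduced study for fast unit tests, cached so multiple
# test files reuse the same objects.

small_config <- function(seed = 11, ...) {
  args <- list(n_tumor_types = 3, samples_per_tumor = 60,
               healthy_per_tissue = 25, n_genes = 120, n_matrisome = 45,
               n_tfs = 25, planted_modules_per_tumor = 5,
               signature_genes_per_tumor = 8, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixtures)) assign(key, make(), envir = .fixtures)
  get(key, envir = .fixtures)
}

small_sim <- function(seed = 11) {
  cached(paste0("sim", seed), function() simulate_study(small_config(seed)))
}

small_pipeline <- function(seed = 11) {
  cached(paste0("pipe", seed),
         function() run_study_pipeline(small_sim(seed), seed = seed))
}

# independent exhaustive Youden-cutpoint search, used as the oracle for
# youden_threshold(): explicit loops over every midpoint cutpoint
brute_force_youden <- function(zin, zrest) {
  pooled <- sort(unique(c(zin, zrest)))
  best_j <- -Inf
  best_cut <- NA_real_
  for (i in seq_len(length(pooled) - 1L)) {
    cut <- (pooled[i] + pooled[i + 1L]) / 2
    sens <- sum(zin > cut) / length(zin)
    spec <- sum(zrest <= cut) / length(zrest)
    j <- sens + spec - 1
    if (j > best_j + 1e-9) {
      best_j <- j
      best_cut <- cut
    }
  }
  list(threshold = best_cut, j_statistic = best_j)
}

# independent brute-force log-rank: sum of observed minus expected deaths in
# one group over event times, with the hypergeometric variance at each time
brute_force_logrank <- function(time, event, grp) {
  g1 <- sort(unique(grp))[1]
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & grp == g1)
    n1 <- sum(at_risk & grp == g1)
    n <- sum(at_risk)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
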