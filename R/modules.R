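#' Fisher z-transform of a Pearson correlation
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)), normalizing the sampling
#' distribution of r before thresholding.
#'
#' @param r correlation value(s) with |r| < 1.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Mine candidate TF-target modules from prior sources
#'
#' A (tf, target) pair becomes a candidate module for a tumor when the
#' target belongs to the tumor's signature, the pair is supported by at
#' least two prior sources, and at least one supporting source is the
#' FANTOM5-like presence table or the TF-binding-site enrichment table.
#'
#' @param priors data.frame `tf`, `target`, `source` (see
#'   [generate_priors()]).
#' @param signature a [infer_signature()] result (or a list with `genes`).
#' @param tumor tumor label attached to the candidates.
#' @return data.frame `tf`, `target`, `tumor`, `sources` (comma-collapsed),
#'   `n_sources`. Empty (with a warning) when the signature is empty.
#' @export
mine_candidates <- function(priors, signature, tumor) {
  empty <- data.frame(tf = character(), target = character(),
                      tumor = character(), sources = character(),
                      n_sources = integer(), stringsAsFactors = FALSE)
  if (length(signature$genes) == 0L) {
    warning("empty signature for tumor ", tumor, ": no candidates mined")
    return(empty)
  }
  hits <- priors[priors$target %in% signature$genes, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  key <- paste(hits$tf, hits$target, sep = "\r")
  src <- split(hits$source, key)
  keep <- vapply(src, function(s) {
    length(unique(s)) >= 2L &&
      any(s %in% c("fantom_presence", "tfbs_enrichment"))
  }, logical(1))
  src <- src[keep]
  if (length(src) == 0L) return(empty)
  parts <- strsplit(names(src), "\r", fixed = TRUE)
  out <- data.frame(
    tf = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    tumor = tumor,
    sources = vapply(src, function(s) paste(sort(unique(s)), collapse = ","),
                     character(1)),
    n_sources = vapply(src, function(s) length(unique(s)), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation filter: in-tumor vs rest-of-cohort Pearson r and Fisher z
#'
#' Computes, per candidate module, the TF-target Pearson correlation over
#' the tumor's primary samples (`r_in`) and over the pooled primary samples
#' of every other tumor (`r_rest`), removes candidates with `r_in <= 0`, and
#' fills the Fisher-z fields. Candidates whose TF or target is constant in
#' either sample pool are removed with a message.
#'
#' @param candidates output of [mine_candidates()].
#' @param expr genes x samples matrix.
#' @param annotation sample annotation.
#' @param tumor the owning tumor.
#' @return candidates with added `r_in`, `r_rest`, `zcor_in`, `zcor_rest`,
#'   positive-correlation candidates only.
#' @export
correlation_filter <- function(candidates, expr, annotation, tumor) {
  in_ids <- annotation$sample_id[annotation$tumor_type == tumor &
                                   annotation$sample_class != "healthy"]
  rest_ids <- annotation$sample_id[annotation$tumor_type != tumor &
                                     annotation$sample_class != "healthy"]
  r_in <- r_rest <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tf <- candidates$tf[i]; tg <- candidates$target[i]
    if (!tf %in% rownames(expr) || !tg %in% rownames(expr)) next
    a_in <- expr[tf, in_ids]; b_in <- expr[tg, in_ids]
    a_rs <- expr[tf, rest_ids]; b_rs <- expr[tg, rest_ids]
    if (stats::sd(a_in) == 0 || stats::sd(b_in) == 0 ||
        stats::sd(a_rs) == 0 || stats::sd(b_rs) == 0) {
      message("candidate ", tf, "->", tg,
              " removed: constant expression vector")
      next
    }
    r_in[i] <- stats::cor(a_in, b_in)
    r_rest[i] <- stats::cor(a_rs, b_rs)
  }
  candidates$r_in <- r_in
  candidates$r_rest <- r_rest
  keep <- !is.na(r_in) & r_in > 0 & abs(r_in) < 1 & abs(r_rest) < 1
  out <- candidates[keep, , drop = FALSE]
  out$zcor_in <- fisher_z(out$r_in)
  out$zcor_rest <- fisher_z(out$r_rest)
  rownames(out) <- NULL
  out
}

#' Youden-index cutpoint between in-tumor and rest-of-cohort z values
#'
#' Candidate cutpoints are the midpoints between consecutive distinct values
#' of the pooled sample. For each cutpoint, sensitivity is the fraction of
#' in-tumor z values strictly above it and specificity the fraction of
#' rest-of-cohort z values at or below it; the cutpoint maximizing Youden's
#' J = sensitivity + specificity - 1 is returned (smallest such cutpoint on
#' ties).
#'
#' @param zcor_in numeric vector of in-tumor Fisher z values.
#' @param zcor_rest numeric vector of rest-of-cohort Fisher z values.
#' @param conf_level echoed in the result for provenance; the cutpoint
#'   itself is a point estimate and does not depend on it.
#' @return list with `threshold` and `j_statistic`.
#' @export
youden_threshold <- function(zcor_in, zcor_rest, conf_level = 0.95) {
  if (length(zcor_in) == 0L || length(zcor_rest) == 0L) {
    stop("both z-value sets must be non-empty")
  }
  pooled <- sort(unique(c(zcor_in, zcor_rest)))
  if (length(pooled) < 2L) {
    stop("all z values identical: no separating cutpoint exists")
  }
  cuts <- (pooled[-1] + pooled[-length(pooled)]) / 2
  sens <- vapply(cuts, function(c) mean(zcor_in > c), numeric(1))
  spec <- vapply(cuts, function(c) mean(zcor_rest <= c), numeric(1))
  j <- sens + spec - 1
  # ties (within floating-point resolution) resolve to the smallest cutpoint
  best <- which(j > max(j) - 1e-9)[1L]
  list(threshold = cuts[best], j_statistic = j[best],
       conf_level = conf_level)
}

#' Adaptive-lasso pruning of a multi-TF target
#'
#' Regresses the target's expression on its candidate TFs' expression with
#' the adaptive lasso: per-coefficient weights w_j = 1/|b_j|^gamma (gamma =
#' 1) from an initial least-squares fit (ridge when the design is
#' rank-deficient), penalty strength by internal cross-validation
#' (`lambda.1se`). TFs with a nonzero coefficient at the selected penalty
#' are retained. Identical TF columns are resolved before fitting: only the
#' lexicographically first of each duplicate group is kept.
#'
#' @param expr_tumor genes x samples matrix restricted to the owning tumor.
#' @param target target gene identifier.
#' @param tfs candidate TF identifiers (single TF returned unchanged).
#' @return character vector of retained TFs.
#' @export
adaptive_lasso_prune <- function(expr_tumor, target, tfs) {
  tfs <- sort(unique(tfs))
  if (length(tfs) <= 1L) return(tfs)
  if (ncol(expr_tumor) < 2L) stop("need at least 2 samples")
  y <- expr_tumor[target, ]
  x <- t(expr_tumor[tfs, , drop = FALSE])

  # deterministic tie-break for duplicated columns: keep the first identifier
  dup <- duplicated(t(x))
  tfs <- tfs[!dup]
  x <- x[, !dup, drop = FALSE]
  if (ncol(x) == 1L) return(tfs)

  n <- length(y)
  init <- stats::coef(stats::lm(y ~ x))[-1]
  if (any(is.na(init)) || n <= ncol(x) + 1L) {
    ridge <- glmnet::cv.glmnet(x, y, alpha = 0, nfolds = min(10L, n),
                               foldid = rep_len(seq_len(min(10L, n)), n))
    init <- as.numeric(stats::coef(ridge, s = "lambda.min"))[-1]
  }
  w <- 1 / abs(init)
  w[!is.finite(w)] <- 1e12
  nfolds <- min(10L, n)
  fit <- glmnet::cv.glmnet(x, y, alpha = 1, penalty.factor = w,
                           foldid = rep_len(seq_len(nfolds), n))
  beta <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1]
  tfs[beta != 0]
}

resample_folds <- function(n, folds, frac, seed) {
  set.seed(seed)
  lapply(seq_len(folds), function(i) sample(n, ceiling(frac * n)))
}

#' Sparse Gaussian network confirmation ("model 2")
#'
#' Score-based structure search over the model-1 variables with candidate
#' edges restricted to model-1 pairs: per target, greedy forward selection
#' of TF parents under the Gaussian BIC score (the BIC penalty induces
#' sparsity). The search is repeated over `folds` random subsamples of the
#' tumor's samples and an edge is reported iff selected in at least
#' `stability` of the folds.
#'
#' @param expr_tumor genes x samples matrix for the owning tumor.
#' @param model1 data.frame of model-1 modules (`tf`, `target`).
#' @param folds number of resampled folds (default 10).
#' @param subsample fraction of samples per fold (default 0.9).
#' @param stability minimum selection frequency (default 0.5).
#' @param seed RNG seed for the resampling.
#' @return data.frame `tf`, `target`, `frequency` of stable edges (a subset
#'   of `model1`).
#' @export
model2_sparse_bayes <- function(expr_tumor, model1, folds = 10L,
                                subsample = 0.9, stability = 0.5, seed = 1L) {
  if (nrow(model1) == 0L) return(model1[, c("tf", "target")])
  n <- ncol(expr_tumor)
  if (n < 20L) stop("structure search unreliable below 20 samples")
  fold_idx <- resample_folds(n, folds, subsample, seed)
  key <- paste(model1$tf, model1$target)
  count <- stats::setNames(integer(length(key)), key)
  targets <- split(model1$tf, model1$target)

  for (idx in fold_idx) {
    sub <- expr_tumor[, idx, drop = FALSE]
    for (tg in names(targets)) {
      parents <- sort(targets[[tg]])
      y <- sub[tg, ]
      chosen <- character()
      current_bic <- stats::BIC(stats::lm(y ~ 1))
      repeat {
        remaining <- setdiff(parents, chosen)
        if (length(remaining) == 0L) break
        bics <- vapply(remaining, function(p) {
          x <- t(sub[c(chosen, p), , drop = FALSE])
          stats::BIC(stats::lm(y ~ x))
        }, numeric(1))
        if (min(bics) >= current_bic) break
        best <- remaining[which.min(bics)]
        chosen <- c(chosen, best)
        current_bic <- min(bics)
      }
      if (length(chosen)) {
        k <- paste(chosen, tg)
        count[k] <- count[k] + 1L
      }
    }
  }
  freq <- count / folds
  out <- model1[freq[key] >= stability, c("tf", "target"), drop = FALSE]
  out$frequency <- freq[paste(out$tf, out$target)]
  rownames(out) <- NULL
  out
}

#' Lasso neighborhood-selection confirmation ("model 3")
#'
#' Pairwise conditional-dependence estimation over the model-1 variables,
#' restricted to model-1 pairs: per target, an L1-penalized regression of
#' the target on its candidate TFs (penalty by internal cross-validation,
#' `lambda.1se`); an edge is selected in a fold iff its coefficient is
#' nonzero (for a single-TF target, iff the marginal correlation is
#' significant at 0.05). The same 10-fold subsample/stability rule as
#' [model2_sparse_bayes()] applies.
#'
#' @inheritParams model2_sparse_bayes
#' @return data.frame `tf`, `target`, `frequency` of stable edges.
#' @export
model3_mixed_graphical <- function(expr_tumor, model1, folds = 10L,
                                   subsample = 0.9, stability = 0.5,
                                   seed = 2L) {
  if (nrow(model1) == 0L) return(model1[, c("tf", "target")])
  n <- ncol(expr_tumor)
  if (n < 20L) stop("structure search unreliable below 20 samples")
  fold_idx <- resample_folds(n, folds, subsample, seed)
  key <- paste(model1$tf, model1$target)
  count <- stats::setNames(integer(length(key)), key)
  targets <- split(model1$tf, model1$target)

  for (idx in fold_idx) {
    sub <- expr_tumor[, idx, drop = FALSE]
    m <- length(idx)
    for (tg in names(targets)) {
      parents <- sort(unique(targets[[tg]]))
      y <- sub[tg, ]
      selected <- character()
      if (length(parents) == 1L) {
        ct <- stats::cor.test(sub[parents, ], y)
        if (!is.na(ct$p.value) && ct$p.value < 0.05) selected <- parents
      } else {
        x <- t(sub[parents, , drop = FALSE])
        nfolds <- min(10L, m)
        fit <- glmnet::cv.glmnet(x, y, alpha = 1,
                                 foldid = rep_len(seq_len(nfolds), m))
        beta <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1]
        selected <- parents[beta != 0]
      }
      if (length(selected)) {
        k <- paste(selected, tg)
        count[k] <- count[k] + 1L
      }
    }
  }
  freq <- count / folds
  out <- model1[freq[key] >= stability, c("tf", "target"), drop = FALSE]
  out$frequency <- freq[paste(out$tf, out$target)]
  rownames(out) <- NULL
  out
}

#' Two-of-three consensus over the inference models
#'
#' A module is final iff present in at least two of the three models. Since
#' models 2 and 3 are restricted to model-1 pairs, this equals
#' model1 intersected with (model2 union model3); pairs presented in models
#' 2/3 but absent from model 1 are dropped.
#'
#' @param model1 data.frame of model-1 modules (`tf`, `target`, plus any
#'   carried columns).
#' @param model2,model3 data.frames with `tf`, `target`.
#' @return `model1` with logical columns `in_model1`, `in_model2`,
#'   `in_model3`, `final`.
#' @export
consensus_modules <- function(model1, model2, model3) {
  key <- function(d) if (nrow(d)) paste(d$tf, d$target) else character()
  k1 <- key(model1)
  model1$in_model1 <- TRUE
  model1$in_model2 <- k1 %in% key(model2)
  model1$in_model3 <- k1 %in% key(model3)
  model1$final <- model1$in_model2 | model1$in_model3
  model1
}

#' Cross-validate module proteins against staining profiles
#'
#' Computes, per module TF or target, the Percentile Positive Staining
#' (PPS): the percentage of assayed immunohistochemistry samples scoring
#' High or Medium. A protein is validated iff PPS > 0. Proteins absent from
#' the staining table are reported as not assayed (distinct from PPS = 0)
#' and excluded from the validation denominator.
#'
#' @param modules data.frame with `tf`, `target`.
#' @param staining data.frame `protein`, `sample_id`, `level`.
#' @return data.frame `protein`, `assayed`, `n_assayed`, `pps`, `validated`.
#' @export
staining_crossval <- function(modules, staining) {
  proteins <- sort(unique(c(modules$tf, modules$target)))
  out <- data.frame(protein = proteins, assayed = FALSE,
                    n_assayed = 0L, pps = NA_real_, validated = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(proteins)) {
    lv <- staining$level[staining$protein == proteins[i]]
    if (length(lv) == 0L) next
    out$assayed[i] <- TRUE
    out$n_assayed[i] <- length(lv)
    out$pps[i] <- 100 * mean(lv %in% c("High", "Medium"))
    out$validated[i] <- out$pps[i] > 0
  }
  out
}
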