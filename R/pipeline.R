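#' Run the full module-inference consensus pipeline for one tumor
#'
#' Chains the stages of the consensus engine: prior mining
#' ([mine_candidates()]), correlation filtering ([correlation_filter()]),
#' Youden-threshold separation of in-tumor versus rest-of-cohort Fisher z
#' values ([youden_threshold()]; retention requires `zcor_in > threshold`
#' and `zcor_in > zcor_rest`), adaptive-lasso pruning of multi-TF targets
#' ([adaptive_lasso_prune()]) yielding model 1, confirmation by the sparse
#' Gaussian network search ([model2_sparse_bayes()]) and lasso neighborhood
#' selection ([model3_mixed_graphical()]), and the two-of-three consensus
#' ([consensus_modules()]).
#'
#' @param expr genes x samples expression matrix.
#' @param annotation sample annotation.
#' @param matrisome matrisome catalog.
#' @param priors prior interaction table.
#' @param tumor tumor to analyse.
#' @param clusters optional tumor -> cluster assignment for the signature's
#'   rest-of-cohort comparison.
#' @param signature optional precomputed [infer_signature()] result; when
#'   `NULL` it is inferred here.
#' @param seed RNG seed for the fold resampling of models 2 and 3.
#' @param folds folds for models 2 and 3.
#' @return list with
#'   \describe{
#'     \item{modules}{data.frame of model-1 modules with `r_in`, `r_rest`,
#'       `zcor_in`, `zcor_rest`, `sources`, `in_model1..3`, `final`.}
#'     \item{counts}{named vector of stage sizes: `mined`,
#'       `post_correlation`, `post_youden`, `model1`, `final`.}
#'     \item{threshold}{the [youden_threshold()] result (or NULL when no
#'       candidates survived the correlation filter).}
#'     \item{signature}{the signature used.}
#'   }
#' @export
infer_modules_pipeline <- function(expr, annotation, matrisome, priors,
                                   tumor, clusters = NULL, signature = NULL,
                                   seed = 1L, folds = 10L) {
  if (is.null(signature)) {
    signature <- infer_signature(expr, annotation, matrisome, tumor,
                                 clusters = clusters)
  }
  empty_counts <- c(mined = 0L, post_correlation = 0L, post_youden = 0L,
                    model1 = 0L, final = 0L)
  empty <- list(modules = data.frame(), counts = empty_counts,
                threshold = NULL, signature = signature)
  if (is.null(signature)) return(empty)

  mined <- mine_candidates(priors, signature, tumor)
  if (nrow(mined) == 0L) return(empty)
  empty$counts["mined"] <- nrow(mined)

  cand <- correlation_filter(mined, expr, annotation, tumor)
  empty$counts["post_correlation"] <- nrow(cand)
  if (nrow(cand) == 0L) {
    empty$counts["mined"] <- nrow(mined)
    return(empty)
  }

  thr <- youden_threshold(cand$zcor_in, cand$zcor_rest)
  kept <- cand[cand$zcor_in > thr$threshold &
                 cand$zcor_in > cand$zcor_rest, , drop = FALSE]

  tum_ids <- annotation$sample_id[annotation$tumor_type == tumor &
                                    annotation$sample_class != "healthy"]
  expr_tumor <- expr[, tum_ids, drop = FALSE]

  # adaptive-lasso pruning, target by target, only where > 1 TF survives
  model1 <- kept
  for (tg in unique(kept$target)) {
    tfs <- kept$tf[kept$target == tg]
    if (length(tfs) > 1L) {
      retained <- adaptive_lasso_prune(expr_tumor, tg, tfs)
      model1 <- model1[model1$target != tg |
                         model1$tf %in% retained, , drop = FALSE]
    }
  }
  rownames(model1) <- NULL

  m2 <- model2_sparse_bayes(expr_tumor, model1, folds = folds,
                            seed = seed + 10L)
  m3 <- model3_mixed_graphical(expr_tumor, model1, folds = folds,
                               seed = seed + 20L)
  modules <- consensus_modules(model1, m2, m3)

  counts <- c(mined = nrow(mined), post_correlation = nrow(cand),
              post_youden = nrow(kept), model1 = nrow(model1),
              final = sum(modules$final))
  list(modules = modules, counts = counts, threshold = thr,
       signature = signature)
}

#' Run signatures and module inference across all tumors of a study
#'
#' Computes the inter-tumor correlation clustering, per-tumor signatures
#' (same-cluster tumors excluded from the rest-of-cohort comparison), and
#' the consensus module pipeline for every tumor with matched healthy
#' samples.
#'
#' @param sim a simulated study from [simulate_study()] (or any list with
#'   `expr`, `annotation`, `matrisome`, `priors`).
#' @param k_cluster genes per tumor for the correlation clustering.
#' @param seed RNG seed passed to the per-tumor pipelines.
#' @param folds folds for models 2 and 3.
#' @return list with `clusters`, `signatures` (per tumor), `results` (per
#'   tumor [infer_modules_pipeline()] outputs) and `modules` (row-bound
#'   final-stage table across tumors).
#' @export
run_study_pipeline <- function(sim, k_cluster = 100L, seed = 1L,
                               folds = 10L) {
  k <- min(k_cluster, nrow(sim$expr))
  cl <- inter_tumor_correlation(sim$expr, sim$annotation, k)
  tumors <- sort(unique(
    sim$annotation$tumor_type[sim$annotation$sample_class != "healthy"]))
  signatures <- lapply(tumors, function(t)
    infer_signature(sim$expr, sim$annotation, sim$matrisome, t,
                    clusters = cl$clusters))
  names(signatures) <- tumors
  results <- lapply(tumors, function(t)
    infer_modules_pipeline(sim$expr, sim$annotation, sim$matrisome,
                           sim$priors, t, clusters = cl$clusters,
                           signature = signatures[[t]], seed = seed,
                           folds = folds))
  names(results) <- tumors
  modules <- do.call(rbind, lapply(results, function(r)
    if (nrow(r$modules)) r$modules else NULL))
  rownames(modules) <- NULL
  list(clusters = cl, signatures = signatures, results = results,
       modules = modules)
}

#' Precision and recall of recovered structures against planted truth
#'
#' Compares a set of inferred (tf, target, tumor) triples with the planted
#' modules of the ground truth.
#'
#' @param modules data.frame with `tf`, `target`, `tumor` (e.g. the `final`
#'   rows of [run_study_pipeline()]'s module table).
#' @param truth ground truth from [generate_cohort()].
#' @return list with `tp`, `n_called`, `n_planted`, `precision`, `recall`.
#' @export
evaluate_module_recovery <- function(modules, truth) {
  planted <- do.call(rbind, lapply(names(truth$planted_modules), function(t) {
    d <- truth$planted_modules[[t]]
    data.frame(tf = d$tf, target = d$target, tumor = t,
               stringsAsFactors = FALSE)
  }))
  pk <- paste(planted$tumor, planted$tf, planted$target)
  ck <- if (nrow(modules)) paste(modules$tumor, modules$tf, modules$target)
  else character()
  tp <- sum(ck %in% pk)
  list(tp = tp, n_called = length(ck), n_planted = length(pk),
       precision = if (length(ck)) tp / length(ck) else NA_real_,
       recall = tp / length(pk))
}
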