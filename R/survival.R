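#' Per-sample activity of a TF-target module
#'
#' The arithmetic mean of the TF's and the target's log2-scale expression,
#' per sample.
#'
#' @param expr genes x samples matrix.
#' @param module list or one-row data.frame with `tf` and `target`.
#' @return named numeric vector of activities, one per sample.
#' @export
module_activity <- function(expr, module) {
  tf <- module$tf[1]; tg <- module$target[1]
  missing <- setdiff(c(tf, tg), rownames(expr))
  if (length(missing)) {
    stop("gene(s) missing from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  colMeans(expr[c(tf, tg), , drop = FALSE])
}

#' Mean-dichotomize activity values into high and low strata
#'
#' The threshold is the cohort mean of the activity; samples strictly above
#' it are labelled `"high"`, samples at or below it `"low"`.
#'
#' @param activity numeric vector (>= 2 values, not all identical).
#' @return character vector of `"high"`/`"low"` labels, named like the
#'   input.
#' @export
dichotomize <- function(activity) {
  if (length(activity) < 2L) stop("need at least 2 samples")
  if (max(activity) == min(activity)) {
    stop("all activity values identical: one stratum would be empty")
  }
  stats::setNames(ifelse(activity > mean(activity), "high", "low"),
                  names(activity))
}

#' Kaplan-Meier / log-rank comparison of high and low strata
#'
#' Two-sample log-rank test between the strata. The direction of a
#' significant association is read off the restricted-mean observed
#' survival: `"noxious"` when the high-activity stratum has the worse
#' survival, `"favorable"` otherwise; it is reported only when the log-rank
#' P is below `alpha`.
#'
#' @param labels `"high"`/`"low"` labels named by sample id (see
#'   [dichotomize()]).
#' @param annotation sample annotation with `sample_id`, `survival_days`,
#'   `event` (1 = death observed).
#' @param alpha significance level gating the direction call.
#' @return list with `statistic` (log-rank chi-square), `p_value`,
#'   `direction` (`NA` when not significant), `raw_direction`, `n_high`,
#'   `n_low`.
#' @export
km_logrank <- function(labels, annotation, alpha = 0.05) {
  ids <- names(labels)
  rows <- match(ids, annotation$sample_id)
  if (anyNA(rows)) stop("labelled samples missing from the annotation")
  time <- annotation$survival_days[rows]
  event <- annotation$event[rows]
  grp <- factor(labels, levels = c("low", "high"))
  if (any(table(grp) == 0L)) stop("both strata must be non-empty")
  if (sum(event) == 0L) stop("no events observed: log-rank undefined")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd_fit$chisq)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ grp)
  rmean <- summary(km, rmean = "common")$table[, "rmean"]
  raw_dir <- if (rmean[["grp=high"]] < rmean[["grp=low"]]) "noxious"
  else "favorable"
  list(statistic = stat, p_value = p,
       direction = if (p < alpha) raw_dir else NA_character_,
       raw_direction = raw_dir,
       n_high = sum(grp == "high"), n_low = sum(grp == "low"))
}

#' Survival screen over a tumor's final modules
#'
#' For every module, averages TF and target expression into an activity,
#' mean-dichotomizes the tumor's samples and runs the log-rank comparison.
#' Raw per-module P values are primary; BH-adjusted values are reported
#' alongside for transparency.
#'
#' @param modules data.frame with `tf`, `target` (one row per module).
#' @param expr genes x samples matrix.
#' @param annotation sample annotation with survival fields.
#' @param tumor tumor whose primary samples are analysed.
#' @param alpha significance level for the direction call.
#' @return data.frame `tf`, `target`, `tumor`, `statistic`, `p_value`,
#'   `p_adj`, `direction`, `raw_direction`, `n_high`, `n_low`.
#' @export
module_survival_screen <- function(modules, expr, annotation, tumor,
                                   alpha = 0.05) {
  ids <- annotation$sample_id[annotation$tumor_type == tumor &
                                annotation$sample_class != "healthy"]
  sub <- expr[, ids, drop = FALSE]
  rows <- lapply(seq_len(nrow(modules)), function(i) {
    act <- module_activity(sub, modules[i, ])
    res <- km_logrank(dichotomize(act), annotation, alpha = alpha)
    data.frame(tf = modules$tf[i], target = modules$target[i], tumor = tumor,
               statistic = res$statistic, p_value = res$p_value,
               direction = res$direction, raw_direction = res$raw_direction,
               n_high = res$n_high, n_low = res$n_low,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("tf", "target", "tumor", "statistic", "p_value", "p_adj",
          "direction", "raw_direction", "n_high", "n_low")]
}

#' Direction consistency of prognostic modules sharing a TF or a target
#'
#' For every TF with two or more significant modules in the tumor, and every
#' target with two or more, checks that the prognostic direction is the same
#' across those modules. Returns the violations; an empty list means the
#' consistency property holds.
#'
#' @param results data.frame from [module_survival_screen()].
#' @param tumor tumor to check.
#' @param alpha significance level defining "significant".
#' @return list with `consistent` (logical) and `violations` (data.frame of
#'   offending hubs: `hub`, `role`, `directions`).
#' @export
direction_consistency <- function(results, tumor, alpha = 0.05) {
  sig <- results[results$tumor == tumor & results$p_value < alpha, ,
                 drop = FALSE]
  viol <- list()
  check <- function(col, role) {
    for (h in unique(sig[[col]])) {
      dirs <- unique(sig$direction[sig[[col]] == h])
      dirs <- dirs[!is.na(dirs)]
      if (length(dirs) > 1L) {
        viol[[length(viol) + 1L]] <<- data.frame(
          hub = h, role = role, directions = paste(sort(dirs), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  check("tf", "tf")
  check("target", "target")
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(hub = character(), role = character(),
               directions = character(), stringsAsFactors = FALSE)
  list(consistent = nrow(violations) == 0L, violations = violations)
}

#' Map the matrisome architecture of a tumor to drugs
#'
#' Assigns each drug-gene interaction to the architecture layer of its gene
#' (master regulators take precedence over TFs, TFs over matrisome genes)
#' and, for FDA-approved cancer drugs, partitions them into on-label (the
#' tumor is among the approved types) versus off-label use. Rows whose gene
#' belongs to no layer are skipped with a warning. The drug table is assumed
#' mechanism-filtered ([load_drug_interactions()]).
#'
#' @param architecture list with character vectors `matrisome`, `tfs`,
#'   `masters` for the tumor.
#' @param drugs mechanism-filtered drug interaction table.
#' @param tumor tumor of interest.
#' @return data.frame `layer`, `drug`, `gene`, `fda_cancer_drug`,
#'   `label_status` (`NA` for non-FDA entries).
#' @export
map_druggability <- function(architecture, drugs, tumor) {
  layer_of <- function(g) {
    if (g %in% architecture$masters) "master"
    else if (g %in% architecture$tfs) "TF"
    else if (g %in% architecture$matrisome) "matrisome"
    else NA_character_
  }
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(drugs))) {
    layer <- layer_of(drugs$gene[i])
    if (is.na(layer)) {
      skipped <- c(skipped, drugs$gene[i])
      next
    }
    fda <- isTRUE(drugs$fda_approved_cancer_drug[i])
    label <- if (!fda) NA_character_ else {
      approved <- strsplit(drugs$approved_tumor_types[i], ",")[[1]]
      if (tumor %in% approved) "on-label" else "off-label"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      layer = layer, drug = drugs$drug[i], gene = drugs$gene[i],
      fda_cancer_drug = fda, label_status = label, stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("drug rows skipped, gene in no layer: ",
            paste(unique(skipped), collapse = ", "))
  }
  if (!length(rows)) {
    return(data.frame(layer = character(), drug = character(),
                      gene = character(), fda_cancer_drug = logical(),
                      label_status = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
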