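#' Filter cancer drivers by mutation frequency
#'
#' Tumor-specific drivers are kept iff their mutation frequency in the tumor
#' of interest is strictly above 5%; pan-cancer drivers iff their frequency
#' in the tumor of interest is strictly above that driver's mean frequency
#' across all tumors of the cohort. Drivers with no frequency recorded for
#' the tumor are skipped with a warning.
#'
#' @param drivers data.frame `gene`, `tumor_type`, `mutation_frequency`,
#'   `driver_class` (see [generate_driver_ppi()]).
#' @param tumor tumor of interest.
#' @return data.frame `gene`, `driver_class`, `frequency` of passing
#'   drivers.
#' @export
filter_drivers <- function(drivers, tumor) {
  out <- list()
  spec <- drivers[drivers$driver_class == "tumor-specific", , drop = FALSE]
  spec <- spec[spec$tumor_type == tumor, , drop = FALSE]
  spec <- spec[spec$mutation_frequency > 0.05, , drop = FALSE]
  if (nrow(spec)) {
    out[[1L]] <- data.frame(gene = spec$gene, driver_class = "tumor-specific",
                            frequency = spec$mutation_frequency,
                            stringsAsFactors = FALSE)
  }
  pan <- drivers[drivers$driver_class == "pan-cancer", , drop = FALSE]
  for (g in unique(pan$gene)) {
    rows <- pan[pan$gene == g, , drop = FALSE]
    f_here <- rows$mutation_frequency[rows$tumor_type == tumor]
    if (length(f_here) == 0L) {
      warning("pan-cancer driver ", g, " has no frequency for ", tumor,
              ": skipped")
      next
    }
    if (f_here[1L] > mean(rows$mutation_frequency)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g, driver_class = "pan-cancer", frequency = f_here[1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), driver_class = character(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Link frequency-passing drivers to module TFs through the PPI network
#'
#' A driver becomes a master regulator iff it physically interacts with
#' strictly more than 10% of the tumor's final-module TFs. Coverage is the
#' fraction of those TFs among the driver's PPI partners.
#'
#' @param candidates output of [filter_drivers()].
#' @param ppi undirected PPI edge list (`protein_a`, `protein_b`).
#' @param tumor_tfs the tumor's module TF identifiers (non-empty).
#' @param tumor tumor label attached to the result.
#' @return data.frame `driver`, `tumor`, `driver_class`, `coverage`,
#'   `tf_partners` (comma-collapsed).
#' @export
link_masters <- function(candidates, ppi, tumor_tfs, tumor = NA_character_) {
  if (length(tumor_tfs) == 0L) stop("tumor_tfs must be non-empty")
  empty <- data.frame(driver = character(), tumor = character(),
                      driver_class = character(), coverage = numeric(),
                      tf_partners = character(), stringsAsFactors = FALSE)
  if (nrow(ppi) == 0L) {
    warning("empty PPI table: no masters can be linked")
    return(empty)
  }
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$gene[i]
    partners <- unique(c(ppi$protein_b[ppi$protein_a == g],
                         ppi$protein_a[ppi$protein_b == g]))
    hit <- intersect(partners, tumor_tfs)
    coverage <- length(hit) / length(tumor_tfs)
    if (coverage > 0.10) {
      out[[length(out) + 1L]] <- data.frame(
        driver = g, tumor = tumor,
        driver_class = candidates$driver_class[i],
        coverage = coverage,
        tf_partners = paste(sort(hit), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize master regulators across tumors
#'
#' Reports per-tumor totals of master regulators, cross-tumor averages of
#' total and tumor-specific masters, the weighted average number of TF
#' partners per master (total TF links over total masters), and the
#' common-versus-unique partition (a master is "common" when it occurs in at
#' least two tumors).
#'
#' @param masters_by_tumor named list, tumor -> [link_masters()] result.
#' @return list with `per_tumor` (data.frame), `avg_total`, `avg_specific`,
#'   `tf_per_master`, `common`, `unique`.
#' @export
regulator_summary <- function(masters_by_tumor) {
  per_tumor <- data.frame(
    tumor = names(masters_by_tumor),
    n_masters = vapply(masters_by_tumor, nrow, integer(1)),
    n_specific = vapply(masters_by_tumor, function(m)
      sum(m$driver_class == "tumor-specific"), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_tumor) <- NULL
  all_masters <- do.call(rbind, Filter(function(m) nrow(m) > 0,
                                       masters_by_tumor))
  if (is.null(all_masters) || nrow(all_masters) == 0L) {
    return(list(per_tumor = per_tumor, avg_total = 0, avg_specific = 0,
                tf_per_master = NA_real_, common = character(),
                unique = character()))
  }
  n_partners <- vapply(strsplit(all_masters$tf_partners, ","), length,
                       integer(1))
  occurrence <- table(unlist(lapply(masters_by_tumor, function(m)
    unique(m$driver))))
  list(per_tumor = per_tumor,
       avg_total = mean(per_tumor$n_masters),
       avg_specific = mean(per_tumor$n_specific),
       tf_per_master = sum(n_partners) / nrow(all_masters),
       common = sort(names(occurrence)[occurrence >= 2]),
       unique = sort(names(occurrence)[occurrence == 1]))
}

#' Cluster-level regulator extraction with a linear SVM
#'
#' Intersects the master-regulator lists of the cluster members (entries not
#' common to all members are discarded), then trains an L2-regularized
#' linear support vector machine to separate the cluster's samples from all
#' other primary samples using the shared regulators' expression, over
#' repeated random 80/20 splits. Reports the mean held-out ROC AUC and
#' normalized predictor importances (mean absolute hyperplane weights).
#'
#' @param masters_by_tumor named list, tumor -> [link_masters()] result.
#' @param expr genes x samples matrix.
#' @param annotation sample annotation.
#' @param cluster_members tumor types forming the cluster (>= 2).
#' @param n_splits random 80/20 splits (default 10).
#' @param cost SVM regularization cost (inverse L2 penalty strength).
#' @param seed RNG seed for the splits.
#' @return list with `regulators`, `importance` (named, sums to 1), `auc`
#'   (mean over splits); empty (with warning) when no shared regulators.
#' @export
cluster_regulator_selection <- function(masters_by_tumor, expr, annotation,
                                        cluster_members, n_splits = 10L,
                                        cost = 1, seed = 1L) {
  if (length(cluster_members) < 2L) stop("a cluster needs >= 2 members")
  lists <- lapply(cluster_members, function(t)
    unique(masters_by_tumor[[t]]$driver))
  shared <- Reduce(intersect, lists)
  shared <- sort(intersect(shared, rownames(expr)))
  if (length(shared) == 0L) {
    warning("no shared master regulators across ",
            paste(cluster_members, collapse = ", "))
    return(list(regulators = character(), importance = numeric(),
                auc = NA_real_))
  }
  tumor_annot <- annotation[annotation$sample_class != "healthy", ]
  x <- t(expr[shared, tumor_annot$sample_id, drop = FALSE])
  y <- factor(ifelse(tumor_annot$tumor_type %in% cluster_members,
                     "cluster", "rest"), levels = c("rest", "cluster"))
  n <- nrow(x)
  set.seed(seed)
  aucs <- numeric(n_splits)
  w_abs <- matrix(0, nrow = n_splits, ncol = length(shared),
                  dimnames = list(NULL, shared))
  for (s in seq_len(n_splits)) {
    idx <- sample(n, floor(0.8 * n))
    std <- standardize_train_test(x[idx, , drop = FALSE],
                                  x[-idx, , drop = FALSE])
    fit <- e1071::svm(x = std$train, y = y[idx], kernel = "linear",
                      cost = cost, scale = FALSE)
    # hyperplane weights: w = t(coefs) %*% SV
    w <- colSums(fit$coefs[, 1] * fit$SV)
    w_abs[s, ] <- abs(w)
    dv <- attr(stats::predict(fit, std$test, decision.values = TRUE),
               "decision.values")
    dec <- dv[, 1]
    # e1071 orients positive decision values toward the first class in the
    # column name; flip so that positive always means "cluster"
    if (startsWith(colnames(dv)[1], "rest")) dec <- -dec
    aucs[s] <- as.numeric(pROC::auc(
      pROC::roc(response = y[-idx], predictor = dec, quiet = TRUE,
                levels = c("rest", "cluster"), direction = "<")))
  }
  imp <- colMeans(w_abs)
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  list(regulators = shared, importance = imp, auc = mean(aucs))
}

#' Hypergeometric pathway over-representation with mutational flags
#'
#' One-sided hypergeometric over-representation P per pathway for a query of
#' regulatory genes (masters + module TFs) against a gene universe, with
#' Benjamini-Hochberg FDR across pathways. A pathway is flagged
#' mutationally activated when at least two cancer-specific master
#' regulators belong to it.
#'
#' @param regulatory_genes query gene set (must lie within `universe`).
#' @param pathway_table named list, pathway -> gene set (see [read_gmt()]).
#' @param universe background gene identifiers.
#' @param specific_masters cancer-specific master genes used for the
#'   mutational-activation flag.
#' @return data.frame `pathway`, `overlap`, `p_value`, `fdr`,
#'   `mutationally_activated`, ordered by `p_value`.
#' @export
pathway_enrichment <- function(regulatory_genes, pathway_table, universe,
                               specific_masters = character()) {
  if (length(pathway_table) == 0L) stop("pathway_table must be non-empty")
  regulatory_genes <- unique(regulatory_genes)
  outside <- setdiff(regulatory_genes, universe)
  if (length(outside)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n_u <- length(unique(universe))
  k <- length(regulatory_genes)
  rows <- lapply(names(pathway_table), function(pw) {
    pw_genes <- intersect(pathway_table[[pw]], universe)
    m <- length(pw_genes)
    q <- length(intersect(regulatory_genes, pw_genes))
    p <- stats::phyper(q - 1, m, n_u - m, k, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = q, p_value = p,
               mutationally_activated =
                 length(intersect(specific_masters, pw_genes)) >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway),
             c("pathway", "overlap", "p_value", "fdr",
               "mutationally_activated")]
  rownames(out) <- NULL
  out
}

#' Read a GMT pathway file
#'
#' @param path GMT-format file (pathway, description, genes...).
#' @return named list, pathway -> gene set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}
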