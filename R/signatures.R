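#' Infer a tumor's matrisome signature
#'
#' For every matrisome gene, runs a two-sided Welch t-test of the tumor's
#' primary samples against (i) its matched healthy samples and (ii) the
#' pooled primary samples of all other tumor types, excluding tumors in the
#' same correlation cluster. P values are Benjamini-Hochberg adjusted
#' separately within each comparison family (all matrisome genes, one tumor,
#' one comparison). A gene enters the signature iff it is up-regulated
#' (positive difference of log2-scale means) with adjusted P below `alpha`
#' in both comparisons.
#'
#' Tumors without matched healthy samples are skipped: the function returns
#' `NULL` with a warning giving the reason, mirroring the exclusion of
#' cohorts with no identifiable healthy tissue.
#'
#' @param expr genes x samples log2-scale expression matrix.
#' @param annotation sample annotation data.frame.
#' @param matrisome matrisome catalog (`gene_id`, `category`).
#' @param tumor tumor type to profile.
#' @param clusters optional named vector, tumor -> cluster label, used to
#'   drop same-cluster tumors from the rest-of-cohort comparison.
#' @param alpha adjusted-P cutoff (default 0.05).
#' @return list of class `"matrisome_signature"` with `tumor`, `genes`
#'   (character vector) and `table` (per-gene statistics: mean differences,
#'   raw and BH-adjusted P for both comparisons, membership flag), or `NULL`
#'   if the tumor has no matched healthy samples.
#' @export
infer_signature <- function(expr, annotation, matrisome, tumor,
                            clusters = NULL, alpha = 0.05) {
  genes <- intersect(matrisome$gene_id, rownames(expr))
  if (length(genes) == 0L) stop("no matrisome genes found in the matrix")

  tum_ids <- annotation$sample_id[annotation$tumor_type == tumor &
                                    annotation$sample_class != "healthy"]
  hlt_ids <- annotation$sample_id[annotation$tumor_type == tumor &
                                    annotation$sample_class == "healthy"]
  if (length(hlt_ids) == 0L) {
    warning("tumor ", tumor, " skipped: no matched healthy samples")
    return(NULL)
  }
  excluded <- tumor
  if (!is.null(clusters) && tumor %in% names(clusters)) {
    excluded <- names(clusters)[clusters == clusters[[tumor]]]
  }
  rest_ids <- annotation$sample_id[
    !(annotation$tumor_type %in% excluded) &
      annotation$sample_class != "healthy"]
  if (length(tum_ids) < 2L || length(hlt_ids) < 2L || length(rest_ids) < 2L) {
    stop("fewer than 2 samples in a compared group for tumor ", tumor)
  }

  one_family <- function(a_mat, b_mat) {
    p <- numeric(length(genes))
    d <- numeric(length(genes))
    for (i in seq_along(genes)) {
      a <- a_mat[i, ]; b <- b_mat[i, ]
      d[i] <- mean(a) - mean(b)
      p[i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1 else
        stats::t.test(a, b)$p.value
    }
    list(diff = d, p = p, p_adj = stats::p.adjust(p, method = "BH"))
  }
  vs_healthy <- one_family(expr[genes, tum_ids, drop = FALSE],
                           expr[genes, hlt_ids, drop = FALSE])
  vs_rest <- one_family(expr[genes, tum_ids, drop = FALSE],
                        expr[genes, rest_ids, drop = FALSE])

  keep <- vs_healthy$diff > 0 & vs_healthy$p_adj < alpha &
    vs_rest$diff > 0 & vs_rest$p_adj < alpha
  table <- data.frame(
    gene_id = genes,
    category = matrisome$category[match(genes, matrisome$gene_id)],
    diff_vs_healthy = vs_healthy$diff, p_vs_healthy = vs_healthy$p,
    p_adj_vs_healthy = vs_healthy$p_adj,
    diff_vs_rest = vs_rest$diff, p_vs_rest = vs_rest$p,
    p_adj_vs_rest = vs_rest$p_adj,
    member = keep, stringsAsFactors = FALSE)
  structure(list(tumor = tumor, genes = genes[keep], table = table),
            class = "matrisome_signature")
}

#' Intersect member signatures into a cluster signature
#'
#' The cluster signature is the exact set intersection of the member
#' tumors' signature gene sets; an empty result is allowed.
#'
#' @param signatures list of [infer_signature()] results (NULL entries are
#'   dropped).
#' @param members character vector of tumor types forming the cluster.
#' @return character vector of shared genes.
#' @export
infer_cluster_signature <- function(signatures, members) {
  sigs <- Filter(Negate(is.null), signatures)
  tumor_of <- vapply(sigs, function(s) s$tumor, character(1))
  sigs <- sigs[tumor_of %in% members]
  if (length(sigs) < 2L) {
    stop("a cluster signature needs >= 2 member signatures")
  }
  Reduce(intersect, lapply(sigs, function(s) s$genes))
}

#' Contingency test of signature composition across matrisome categories
#'
#' Builds the tumor x matrisome-category count table of signature members
#' and passes it to [contingency_test()].
#'
#' @param signatures list of [infer_signature()] results.
#' @param matrisome matrisome catalog.
#' @return result of [contingency_test()] plus the count table.
#' @export
signature_composition_test <- function(signatures, matrisome) {
  sigs <- Filter(Negate(is.null), signatures)
  if (length(sigs) < 2L) stop("need >= 2 signatures")
  counts <- t(sapply(sigs, function(s) {
    cats <- matrisome$category[match(s$genes, matrisome$gene_id)]
    table(factor(cats, levels = sort(unique(matrisome$category))))
  }))
  rownames(counts) <- vapply(sigs, function(s) s$tumor, character(1))
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  res <- contingency_test(counts)
  res$counts <- counts
  res
}
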