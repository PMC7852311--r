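#!/usr/bin/env Rscript
# Global expression landscape: per-tumor gene ranking, inter-tumor
# correlation clustering on the top-expressed matrisome genes, and
# three-classifier recall with a contingency test on the pooled confusion.

source("analysis/00_settings.R")

sim <- get_study()
mat_expr <- sim$expr[sim$matrisome$gene_id, ]

top <- rank_genes_per_tumor(mat_expr, sim$annotation, 100)
write_tsv(data.frame(tumor_type = rep(names(top), lengths(top)),
                     rank = unlist(lapply(top, seq_along)),
                     gene_id = unlist(top)),
          file.path(RESULTS_DIR, "landscape_top_genes.tsv"))

cl <- inter_tumor_correlation(sim$expr, sim$annotation, 100)
write_tsv(data.frame(tumor_type = rownames(cl$correlation),
                     round(cl$correlation, 4)),
          file.path(RESULTS_DIR, "landscape_correlation.tsv"))
write_tsv(data.frame(tumor_type = names(cl$clusters),
                     cluster = unname(cl$clusters)),
          file.path(RESULTS_DIR, "landscape_clusters.tsv"))
message("clusters at cut 0.5 on 1 - r: ",
        paste(names(cl$clusters), cl$clusters, sep = "=", collapse = ", "))

res <- classify_tumors(mat_expr, sim$annotation,
                       n_runs = c(svm = 20L, nnet = 5L, tree = 5L),
                       seed = STUDY_SEED)
write_tsv(res$recall, file.path(RESULTS_DIR, "landscape_recall.tsv"))
write_tsv(as.data.frame.matrix(res$confusion),
          file.path(RESULTS_DIR, "landscape_confusion.tsv"))
message(sprintf("mean recall across tumors and algorithms: %.1f%%",
                100 * mean(res$recall$mean_recall)))
ct <- contingency_test(res$confusion)
message(sprintf("confusion contingency: chi-square = %.1f, P = %.3g",
                ct$statistic, ct$p_value))
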