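#' Rank genes by mean expression within each tumor type
#'
#' Computes, per tumor type and over non-healthy samples only, the average
#' expression of each gene and returns the k most- (or least-) expressed
#' genes, ordered. Ties are broken lexicographically by gene identifier.
#'
#' @param expr genes x samples expression matrix.
#' @param annotation sample annotation data.frame (see [generate_cohort()]).
#' @param k how many genes to return per tumor.
#' @param direction `"most"` (descending means) or `"least"` (ascending).
#' @return named list, tumor type -> ordered character vector of k genes.
#' @export
rank_genes_per_tumor <- function(expr, annotation, k,
                                 direction = c("most", "least")) {
  direction <- match.arg(direction)
  if (k > nrow(expr)) {
    stop("k (", k, ") exceeds the number of genes (", nrow(expr), ")")
  }
  tumor_annot <- annotation[annotation$sample_class != "healthy", ]
  tumors <- sort(unique(tumor_annot$tumor_type))
  out <- lapply(tumors, function(t) {
    cols <- tumor_annot$sample_id[tumor_annot$tumor_type == t]
    means <- rowMeans(expr[, cols, drop = FALSE])
    ord <- order(if (direction == "most") -means else means, names(means))
    names(means)[ord][seq_len(k)]
  })
  stats::setNames(out, tumors)
}

#' Inter-tumor correlation and clustering on top-expressed genes
#'
#' Builds the union of each tumor's k most-expressed genes, computes the
#' tumor x tumor Pearson correlation of mean-expression vectors over that
#' universe, and clusters tumors by average-linkage agglomeration on the
#' distance 1 - r, cut at `cut_height`.
#'
#' @inheritParams rank_genes_per_tumor
#' @param cut_height dendrogram cut height on the 1 - r scale (default 0.5,
#'   i.e. tumors join a cluster while their average correlation exceeds 0.5).
#' @param direction ranking direction for the gene universe.
#' @return list with `correlation` (symmetric matrix, unit diagonal),
#'   `clusters` (named integer vector, tumor -> cluster label) and `k_genes`.
#' @export
inter_tumor_correlation <- function(expr, annotation, k, cut_height = 0.5,
                                    direction = "most") {
  tumor_annot <- annotation[annotation$sample_class != "healthy", ]
  tumors <- sort(unique(tumor_annot$tumor_type))
  if (length(tumors) < 2L) stop("need at least 2 tumor types")
  top <- rank_genes_per_tumor(expr, annotation, k, direction)
  universe <- sort(unique(unlist(top)))
  mean_mat <- sapply(tumors, function(t) {
    cols <- tumor_annot$sample_id[tumor_annot$tumor_type == t]
    rowMeans(expr[universe, cols, drop = FALSE])
  })
  sds <- apply(mean_mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("correlation undefined: constant mean-expression vector for tumor ",
         paste(tumors[sds == 0], collapse = ", "))
  }
  r <- stats::cor(mean_mat)
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  clusters <- stats::cutree(hc, h = cut_height)
  list(correlation = r, clusters = clusters[tumors], k_genes = k)
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = scale(train, center = mu, scale = sd),
       test = scale(test, center = mu, scale = sd))
}

fit_predict_one <- function(algorithm, x_train, y_train, x_test) {
  if (algorithm == "svm") {
    fit <- e1071::svm(x = x_train, y = y_train, kernel = "radial",
                      scale = FALSE)
    as.character(stats::predict(fit, x_test))
  } else if (algorithm == "nnet") {
    fit <- nnet::nnet(x = x_train, y = stats::model.matrix(~ y_train - 1),
                      size = 4, maxit = 250, trace = FALSE, softmax = TRUE,
                      MaxNWts = 1e5, decay = 0.01)
    levels(y_train)[apply(stats::predict(fit, x_test), 1, which.max)]
  } else if (algorithm == "tree") {
    df <- data.frame(y = y_train, x_train, check.names = FALSE)
    fit <- rpart::rpart(y ~ ., data = df, method = "class")
    as.character(stats::predict(
      fit, data.frame(x_test, check.names = FALSE), type = "class"))
  } else {
    stop("unknown algorithm: ", algorithm)
  }
}

#' Multi-classifier tumor-type recall with repeated random cross-validation
#'
#' Classifies samples into tumor types with up to three algorithms (an
#' RBF-kernel support vector machine, a single-hidden-layer neural network,
#' and a recursive-partitioning decision tree standing in the
#' classification-tree slot), each over repeated random 80/20 train/test
#' splits. Features are standardized using training-fold statistics only.
#' Per-run per-tumor recalls are averaged within each algorithm and then,
#' unweighted, across algorithms; confusion counts are pooled over all runs
#' and algorithms.
#'
#' @param expr genes x samples matrix (typically restricted to matrisome
#'   genes, mirroring the matrisome-only feature space).
#' @param annotation sample annotation; healthy samples are excluded.
#' @param algorithms subset of `c("svm", "nnet", "tree")`.
#' @param n_runs named integer vector of split repetitions per algorithm;
#'   defaults mirror the reference protocol (100 for the margin classifier,
#'   10 for the others).
#' @param train_frac training fraction per split.
#' @param seed RNG seed for the random splits.
#' @return list with `recall` (data.frame: tumor, one recall column per
#'   algorithm, `mean_recall`) and `confusion` (true x predicted counts).
#' @export
classify_tumors <- function(expr, annotation,
                            algorithms = c("svm", "nnet", "tree"),
                            n_runs = c(svm = 100L, nnet = 10L, tree = 10L),
                            train_frac = 0.8, seed = 1L) {
  tumor_annot <- annotation[annotation$sample_class != "healthy", ]
  tumors <- sort(unique(tumor_annot$tumor_type))
  tab <- table(tumor_annot$tumor_type)
  if (any(tab < 5L)) {
    stop("every tumor type needs >= 5 samples; offending: ",
         paste(names(tab)[tab < 5L], collapse = ", "))
  }
  x <- t(expr[, tumor_annot$sample_id, drop = FALSE])
  y <- factor(tumor_annot$tumor_type, levels = tumors)
  n <- nrow(x)
  set.seed(seed)

  confusion <- matrix(0L, length(tumors), length(tumors),
                      dimnames = list(true = tumors, predicted = tumors))
  recall_by_alg <- list()
  for (alg in algorithms) {
    runs <- if (alg %in% names(n_runs)) n_runs[[alg]] else 10L
    per_run <- matrix(NA_real_, nrow = runs, ncol = length(tumors),
                      dimnames = list(NULL, tumors))
    for (r in seq_len(runs)) {
      idx <- sample(n, floor(train_frac * n))
      std <- standardize_train_test(x[idx, , drop = FALSE],
                                    x[-idx, , drop = FALSE])
      pred <- fit_predict_one(alg, std$train, y[idx], std$test)
      truth <- as.character(y[-idx])
      for (t in unique(truth)) {
        sel <- truth == t
        per_run[r, t] <- mean(pred[sel] == t)
        for (p in unique(pred[sel])) {
          confusion[t, p] <- confusion[t, p] + sum(pred[sel] == p)
        }
      }
    }
    rec <- colMeans(per_run, na.rm = TRUE)
    missed <- colSums(!is.na(per_run)) == 0L
    if (any(missed)) {
      warning("tumor(s) absent from every test split for ", alg, ": ",
              paste(tumors[missed], collapse = ", "))
      rec[missed] <- NA_real_
    }
    recall_by_alg[[alg]] <- rec
  }

  recall <- data.frame(tumor_type = tumors, stringsAsFactors = FALSE)
  for (alg in algorithms) {
    recall[[paste0("recall_", alg)]] <- recall_by_alg[[alg]]
  }
  recall$mean_recall <- rowMeans(
    as.matrix(recall[, paste0("recall_", algorithms), drop = FALSE]),
    na.rm = TRUE)
  list(recall = recall, confusion = confusion)
}

#' Chi-square contingency test with Yates correction on 2x2 tables
#'
#' Applies the Pearson chi-square test to a two-dimensional count table,
#' with Yates continuity correction when (and only when) the table is 2x2.
#'
#' @param counts matrix-like table of non-negative counts.
#' @return list with `statistic`, `p_value`, `df`, `method`.
#' @export
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  if (length(dim(counts)) != 2L || nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("counts must be a table with at least 2 rows and 2 columns")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero-margin row or column: chi-square test undefined")
  }
  yates <- all(dim(counts) == c(2L, 2L))
  res <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter),
       method = if (yates) "chi-square with Yates continuity correction"
       else "Pearson chi-square")
}
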