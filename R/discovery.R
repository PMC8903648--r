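#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values for multiple testing by the step-up procedure
#' controlling the false discovery rate: sort ascending, take
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, and return in input
#' order. The family is all features tested in one comparison run.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

## Exact two-sided rank-sum p is delegated to wilcox.test's exact mode;
## this helper only decides which mode applies: exact when both groups are
## small (<= 10) and there are no ties, normal approximation otherwise.
.wilcox_p <- function(x, y, paired = FALSE, exact_max_n = 10) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties &&
    (if (paired) length(x) <= exact_max_n
     else length(x) <= exact_max_n && length(y) <= exact_max_n)
  suppressWarnings(stats::wilcox.test(
    x, y, paired = paired, exact = use_exact,
    correct = !use_exact)$p.value)
}

#' Differential expression between two phenotype groups
#'
#' Per-feature two-group comparison (e.g. Tumor vs Non-Tumor) on a
#' log2-scale matrix. Raw p-values come from the configured test:
#' `student_t` (Welch unequal-variance form by default; set
#' `var_equal = TRUE` for the pooled form), `wilcoxon_ranksum` (exact
#' enumeration when both groups have <= 10 samples and no ties, otherwise
#' the normal approximation with continuity and tie correction), or their
#' paired variants `paired_t` / `wilcoxon_signed_rank` (which require
#' `paired_by`, a phenotype whose values match samples across groups).
#' Adjusted p-values use [benjamini_hochberg()] across all tested features
#' of the run. The log2 fold change is the difference of group medians
#' (`fc_method = "mean"` selects means), group 1 minus group 2, so
#' `direction = "up"` means higher in group 1.
#'
#' A feature is called significant ("up"/"down") when its adjusted p-value
#' is below `adj_p_threshold` and its fold change exceeds `fc_threshold`
#' (default gate: fold change > 1.5 and adjusted p < 0.01). Features with
#' fewer than 2 data points in either group are reported untested
#' (`tested = FALSE`), not dropped silently.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param p A [phenotype_table()] covering the samples of `m`.
#' @param phenotype Name of the categorical phenotype defining the groups.
#' @param group1,group2 The two level labels to compare (group1 vs group2).
#' @param test One of `"student_t"`, `"wilcoxon_ranksum"`, `"paired_t"`,
#'   `"wilcoxon_signed_rank"`.
#' @param fc_threshold Fold-change gate, > 1 (default 1.5).
#' @param adj_p_threshold Adjusted-p gate in (0, 1) (default 0.01).
#' @param paired_by For paired tests: name of the phenotype holding the
#'   pairing key; every key must appear exactly once in each group.
#' @param fc_method `"median"` (default) or `"mean"` group summary for the
#'   fold change.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return Object of class `de_result`: data.frame with one row per
#'   feature (`feature`, `n1`, `n2`, `median_g1`, `median_g2`, `log2_fc`,
#'   `fold_change`, `raw_p`, `adj_p`, `direction`, `tested`), thresholds
#'   kept as attributes.
#' @export
differential_expression <- function(m, p, phenotype, group1, group2,
                                    test = c("student_t", "wilcoxon_ranksum",
                                             "paired_t", "wilcoxon_signed_rank"),
                                    fc_threshold = 1.5, adj_p_threshold = 0.01,
                                    paired_by = NULL, fc_method = c("median", "mean"),
                                    var_equal = FALSE) {
  stopifnot(inherits(m, "expr_matrix"), inherits(p, "phenotype_table"))
  test <- match.arg(test)
  fc_method <- match.arg(fc_method)
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stop("'fc_threshold' must be > 1")
  if (!is.numeric(adj_p_threshold) || adj_p_threshold <= 0 || adj_p_threshold >= 1)
    stop("'adj_p_threshold' must be in (0, 1)")
  if (!phenotype %in% names(p)) stop("unknown phenotype: ", phenotype)
  paired <- test %in% c("paired_t", "wilcoxon_signed_rank")
  if (paired && is.null(paired_by))
    stop("paired test '", test, "' requires 'paired_by'")

  shared <- intersect(rownames(m), rownames(p))
  labels <- stats::setNames(p[[phenotype]], rownames(p))[shared]
  for (g in c(group1, group2))
    if (!g %in% labels)
      stop("unknown group level '", g, "' in phenotype '", phenotype, "'")
  s1 <- shared[!is.na(labels) & labels == group1]
  s2 <- shared[!is.na(labels) & labels == group2]

  if (paired) {
    key <- stats::setNames(as.character(p[[paired_by]]), rownames(p))
    k1 <- key[s1]; k2 <- key[s2]
    orphans <- c(setdiff(k1, k2), setdiff(k2, k1))
    if (length(orphans) || anyDuplicated(k1) || anyDuplicated(k2))
      stop("paired test has unmatched or duplicated pairing keys: ",
           paste(unique(c(orphans, k1[duplicated(k1)], k2[duplicated(k2)])),
                 collapse = ", "))
    s2 <- s2[match(k1, k2)]  # align group2 to group1's pairing order
  }

  X1 <- unclass(m)[s1, , drop = FALSE]
  X2 <- unclass(m)[s2, , drop = FALSE]
  summ <- if (fc_method == "median") function(x) stats::median(x) else mean
  feats <- colnames(m)
  n1 <- n2 <- integer(length(feats))
  med1 <- med2 <- raw_p <- rep(NA_real_, length(feats))
  tested <- logical(length(feats))
  for (f in seq_along(feats)) {
    x1 <- X1[, f]; x2 <- X2[, f]
    if (paired) {
      ok <- !is.na(x1) & !is.na(x2)
      x1p <- x1[ok]; x2p <- x2[ok]
      n1[f] <- n2[f] <- sum(ok)
      if (sum(ok) < 2) next
      med1[f] <- summ(x1p); med2[f] <- summ(x2p)
      if (stats::sd(x1p - x2p) == 0 && test == "paired_t") {
        raw_p[f] <- if (all(x1p == x2p)) 1 else 0
      } else {
        raw_p[f] <- switch(test,
          paired_t = stats::t.test(x1p, x2p, paired = TRUE)$p.value,
          wilcoxon_signed_rank = .wilcox_p(x1p, x2p, paired = TRUE))
      }
      tested[f] <- TRUE
    } else {
      x1p <- x1[!is.na(x1)]; x2p <- x2[!is.na(x2)]
      n1[f] <- length(x1p); n2[f] <- length(x2p)
      if (length(x1p) < 2 || length(x2p) < 2) next
      med1[f] <- summ(x1p); med2[f] <- summ(x2p)
      if (test == "student_t" && stats::sd(x1p) == 0 && stats::sd(x2p) == 0) {
        raw_p[f] <- if (mean(x1p) == mean(x2p)) 1 else 0
      } else {
        raw_p[f] <- switch(test,
          student_t = stats::t.test(x1p, x2p, var.equal = var_equal)$p.value,
          wilcoxon_ranksum = .wilcox_p(x1p, x2p))
      }
      tested[f] <- TRUE
    }
  }
  adj_p <- rep(NA_real_, length(feats))
  adj_p[tested] <- benjamini_hochberg(raw_p[tested])
  log2_fc <- med1 - med2
  lfc_gate <- log2(fc_threshold)
  direction <- rep("ns", length(feats))
  sig <- tested & !is.na(adj_p) & adj_p < adj_p_threshold
  direction[sig & log2_fc > lfc_gate] <- "up"
  direction[sig & log2_fc < -lfc_gate] <- "down"
  out <- data.frame(feature = feats, n1 = n1, n2 = n2,
                    median_g1 = med1, median_g2 = med2,
                    log2_fc = log2_fc, fold_change = 2^log2_fc,
                    raw_p = raw_p, adj_p = adj_p,
                    direction = direction, tested = tested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, test = test, fc_threshold = fc_threshold,
            adj_p_threshold = adj_p_threshold,
            groups = c(group1, group2),
            class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  if (!all(c("direction", "tested") %in% names(x))) {
    print(as.data.frame(x))
    return(invisible(x))
  }
  g <- attr(x, "groups")
  cat(sprintf("de_result: %s vs %s (%s), %d features (%d up, %d down, %d untested)\n",
              g[1], g[2], attr(x, "test"), nrow(x),
              sum(x$direction == "up"), sum(x$direction == "down"),
              sum(!x$tested)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  c(n_features = nrow(object), n_tested = sum(object$tested),
    n_up = sum(object$direction == "up"),
    n_down = sum(object$direction == "down"))
}

#' Principal component analysis with feature contribution scores
#'
#' Decomposes the (feature-mean-centered) matrix by singular value
#' factorization and ranks features by the contribution score
#' \deqn{S_j = \sum_{i=1}^{n} VR_i \cdot \frac{|V_{ij}|}{\sum_{j=1}^{m} |V_{ij}|}}
#' where \eqn{VR_i} is the explained variance ratio of component \eqn{i}
#' and \eqn{V_{ij}} the loading of feature \eqn{j} on component \eqn{i}.
#' Summed over features, the scores conserve the retained explained
#' variance: \eqn{\sum_j S_j = \sum_{i=1}^n VR_i}. The top-scoring
#' features (default 100) are the PCA-derived candidate set for phenotype
#' association; the 10 largest-loading features per component are also
#' reported.
#'
#' Features are centered but not unit-scaled by default (log2 abundances
#' share a scale); set `scale_features = TRUE` to z-score them first.
#'
#' @param m A complete (no missing values) [expression_matrix()] with
#'   >= 2 samples.
#' @param n_components Number of retained components; clipped with a
#'   warning to `min(n_samples - 1, n_features)`.
#' @param top_k Length of the `top_features` list (default 100).
#' @param scale_features Unit-scale features before decomposition.
#' @return Object of class `pca_result`: list with
#'   `explained_variance_ratio` (all components), `loadings` (components x
#'   features), `scores` (samples x components), `contribution`
#'   (data.frame feature/score, input order), `top_features`,
#'   `top_per_component` (list of 10 feature ids per retained component),
#'   `n_components`.
#' @export
pca_contribution <- function(m, n_components = 10, top_k = 100,
                             scale_features = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (anyNA(m)) stop("PCA requires a complete matrix; impute first")
  if (nrow(m) < 2) stop("PCA requires >= 2 samples")
  X <- unclass(m)
  if (all(apply(X, 2, stats::sd) == 0))
    stop("constant matrix: no variance to decompose")
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_comp) {
    warning("n_components clipped from ", n_components, " to ", max_comp)
    n_components <- max_comp
  }
  if (n_components < 1) stop("'n_components' must be >= 1")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale_features)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  V <- t(pc$rotation)                # components x features
  ret <- seq_len(n_components)
  absV <- abs(V[ret, , drop = FALSE])
  norm <- absV / rowSums(absV)       # each retained row sums to 1
  S <- as.numeric(vr[ret] %*% norm)
  names(S) <- colnames(m)
  ord <- order(S, decreasing = TRUE)
  top_per_component <- lapply(ret, function(i) {
    colnames(m)[order(abs(V[i, ]), decreasing = TRUE)[seq_len(min(10, ncol(m)))]]
  })
  names(top_per_component) <- rownames(V)[ret]
  structure(list(
    explained_variance_ratio = vr,
    loadings = V,
    scores = pc$x,
    contribution = data.frame(feature = colnames(m), score = unname(S),
                              stringsAsFactors = FALSE),
    top_features = colnames(m)[ord[seq_len(min(top_k, ncol(m)))]],
    top_per_component = top_per_component,
    n_components = n_components),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vr <- x$explained_variance_ratio[seq_len(x$n_components)]
  cat(sprintf("pca_result: %d retained components (VR %s), %d top features\n",
              x$n_components,
              paste(sprintf("%.3f", vr[seq_len(min(5, length(vr)))]),
                    collapse = ", "),
              length(x$top_features)))
  invisible(x)
}

#' Z-score feature profiles across samples
#'
#' Per-feature standardization `(x - mean) / sd` across samples using the
#' sample (n-1) standard deviation, the conventional preparation for
#' expression-pattern clustering and heatmaps.
#'
#' @param m A complete [expression_matrix()].
#' @return Numeric matrix, same shape; each column has mean 0 and sd 1.
#' @export
zscore_features <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (anyNA(m)) stop("z-scoring requires a complete matrix; impute first")
  X <- unclass(m)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s), cannot z-score: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Hierarchical feature clustering
#'
#' Groups features sharing similar expression patterns: each feature
#' profile is z-score transformed across samples, features are clustered
#' agglomeratively (Euclidean distance, Ward linkage) and the tree is cut
#' into `k` user-defined flat clusters. Per-cluster feature lists feed the
#' downstream enrichment analysis.
#'
#' @param m A complete [expression_matrix()] with no constant features.
#' @param k Number of flat clusters, in \[1, number of features\].
#' @return Object of class `cluster_result`: list with `assignments`
#'   (named integer vector feature -> cluster id in 1..k), `k`, `sets`
#'   (list of feature ids per cluster), and the `hclust` tree.
#' @export
cluster_features <- function(m, k) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > ncol(m))
    stop("'k' must lie in [1, ", ncol(m), "] (the feature count)")
  k <- as.integer(k)
  Z <- t(zscore_features(m))     # features x samples
  tree <- stats::hclust(stats::dist(Z, method = "euclidean"),
                        method = "ward.D2")
  assignments <- stats::cutree(tree, k = k)
  sets <- split(names(assignments), assignments)
  names(sets) <- paste0("cluster_", names(sets))
  structure(list(assignments = assignments, k = k, sets = sets,
                 tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- vapply(x$sets, length, 0L)
  cat(sprintf("cluster_result: %d features in %d clusters (sizes %s)\n",
              length(x$assignments), x$k, paste(sizes, collapse = ", ")))
  invisible(x)
}
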