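#' Rank-based ROC AUC
#'
#' Area under the receiver operating characteristic curve computed from
#' the Mann-Whitney statistic with midranks for ties:
#' `AUC = (sum of positive ranks - n_pos(n_pos+1)/2) / (n_pos * n_neg)`,
#' the probability that a random positive outscores a random negative
#' (ties counting one half). ROC points are emitted at every distinct
#' score threshold.
#'
#' @param scores Numeric vector of per-sample scores (higher = more
#'   positive).
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second sorted level is positive).
#' @return Object of class `roc_result`: list with `auc`, `points`
#'   (data.frame `threshold`, `fpr`, `tpr`, anchored at (0,0) and (1,1)),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary_labels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires both classes present (got ", n_pos, " positives, ",
         n_neg, " negatives)")
  r <- rank(scores)                       # midranks for ties
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & y == 0) / n_neg, tpr = sum(pred & y == 1) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  points <- data.frame(threshold = c(Inf, thr, -Inf),
                       fpr = c(0, pts[, "fpr"], 1),
                       tpr = c(0, pts[, "tpr"], 1))
  structure(list(auc = auc, points = unique(points),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d positives vs %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

.as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lev <- sort(unique(labels[!is.na(labels)]))
    if (length(lev) != 2)
      stop("labels must have exactly 2 levels, got ", length(lev))
    return(ifelse(is.na(labels), NA_integer_,
                  as.integer(labels == lev[2])))
  }
  u <- unique(labels[!is.na(labels)])
  if (!all(u %in% c(0, 1)))
    stop("numeric labels must be 0/1")
  as.integer(labels)
}

#' Univariate logistic regression of a binary phenotype on one feature
#'
#' Maximum-likelihood fit of `P(y = 1 | x) = 1 / (1 + exp(-(a + b x)))`
#' by iteratively reweighted least squares (at most 100 iterations,
#' convergence when the deviance change falls below 1e-8). Complete
#' separation makes the likelihood unbounded; the last iterate is then
#' returned with `separation = TRUE` — its fitted probabilities remain
#' monotone in `x`, so ranking metrics such as the AUC are still valid.
#'
#' @param x Numeric feature values.
#' @param y Binary labels (see [roc_auc()] for accepted encodings).
#' @return Object of class `logistic_fit`: list with `intercept`, `slope`,
#'   `probabilities` (per retained sample), `separation`, `converged`,
#'   `n`.
#' @export
logistic_fit <- function(x, y) {
  y <- .as_binary_labels(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(y)) < 2)
    stop("logistic fit requires both classes present")
  if (sum(y == 1) < 3 || sum(y == 0) < 3)
    stop("logistic fit requires >= 3 samples per class")
  if (stats::sd(x) == 0)
    stop("constant feature: logistic slope is undefined")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 probabilities = unname(stats::fitted(fit)),
                 separation = separation || !fit$converged,
                 converged = fit$converged,
                 n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: logit(p) = %.4g %+.4g x (n = %d%s)\n",
              x$intercept, x$slope, x$n,
              if (x$separation) ", separation" else ""))
  invisible(x)
}

#' Correlation screen of one feature against a binary phenotype
#'
#' Pearson correlation (point-biserial, since the phenotype is encoded
#' 0/1) between a feature and a two-level categorical phenotype over the
#' samples non-missing in both, with the p-value from the t-approximation.
#' The feature is flagged phenotype-associated when p < `alpha` (default
#' 0.05). A constant feature or constant phenotype over the shared samples
#' yields an undefined correlation and is never counted associated.
#'
#' @param x Numeric feature values.
#' @param y Binary phenotype (see [roc_auc()] for encodings).
#' @param alpha Association significance level.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `associated`, `n`.
#' @export
feature_phenotype_correlation <- function(x, y, alpha = 0.05,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  y <- .as_binary_labels(y)
  ok <- !is.na(x) & !is.na(y)
  xs <- x[ok]; ys <- y[ok]
  if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0)
    return(list(r = NA_real_, p_value = NA_real_, associated = FALSE,
                n = length(xs)))
  ct <- suppressWarnings(stats::cor.test(xs, ys, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       associated = is.finite(ct$p.value) && ct$p.value < alpha,
       n = length(xs))
}

#' Per-feature phenotype association table
#'
#' Runs the full per-feature association battery — correlation screen,
#' univariate logistic regression and in-sample ROC AUC — for a set of
#' features (typically the union of the differential-expression calls, the
#' PCA top contributors and selected cluster sets) against a categorical
#' phenotype. A two-level phenotype yields one contrast; a multi-level
#' phenotype is expanded one-vs-rest, each contrast reported separately
#' (`contrast` column `level_vs_rest`).
#'
#' Features whose logistic fit is impossible (constant values, a class
#' with < 3 samples) keep their correlation fields with `NA` model fields.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param p A [phenotype_table()].
#' @param phenotype Name of a categorical phenotype.
#' @param features Feature ids to test; `NULL` tests every feature.
#' @param alpha Correlation significance level (default 0.05).
#' @param method Correlation flavor passed to
#'   [feature_phenotype_correlation()].
#' @return Object of class `association_result`: data.frame with columns
#'   `feature`, `contrast`, `r`, `p_value`, `associated`, `intercept`,
#'   `slope`, `separation`, `auc`, `n`.
#' @export
associate_features <- function(m, p, phenotype, features = NULL,
                               alpha = 0.05,
                               method = c("pearson", "spearman")) {
  stopifnot(inherits(m, "expr_matrix"), inherits(p, "phenotype_table"))
  method <- match.arg(method)
  if (!phenotype %in% names(p)) stop("unknown phenotype: ", phenotype)
  if (phenotype_kinds(p)[[phenotype]] != "categorical")
    stop("'", phenotype, "' is not categorical")
  if (is.null(features)) features <- colnames(m)
  missing_f <- setdiff(features, colnames(m))
  if (length(missing_f))
    stop("feature(s) not in matrix: ", paste(missing_f, collapse = ", "))
  shared <- intersect(rownames(m), rownames(p))
  lab <- stats::setNames(as.character(p[[phenotype]]), rownames(p))[shared]
  lev <- sort(unique(lab[!is.na(lab)]))
  if (length(lev) < 2)
    stop("phenotype '", phenotype, "' has < 2 levels over shared samples")
  contrasts <- if (length(lev) == 2)
    list(stats::setNames(list(ifelse(lab == lev[2], 1L, 0L)),
                         paste0(lev[2], "_vs_", lev[1])))[[1]]
  else {
    cs <- lapply(lev, function(l) ifelse(lab == l, 1L, 0L))
    stats::setNames(cs, paste0(lev, "_vs_rest"))
  }
  rows <- list()
  for (cn in names(contrasts)) {
    ybin <- contrasts[[cn]]
    for (f in features) {
      x <- unclass(m)[shared, f]
      cr <- feature_phenotype_correlation(x, ybin, alpha = alpha,
                                          method = method)
      lf <- try(logistic_fit(x, ybin), silent = TRUE)
      if (inherits(lf, "try-error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, contrast = cn, r = cr$r, p_value = cr$p_value,
          associated = cr$associated, intercept = NA_real_,
          slope = NA_real_, separation = NA, auc = NA_real_, n = cr$n,
          stringsAsFactors = FALSE)
      } else {
        ok <- !is.na(x) & !is.na(ybin)
        auc <- roc_auc(lf$probabilities, ybin[ok])$auc
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, contrast = cn, r = cr$r, p_value = cr$p_value,
          associated = cr$associated, intercept = lf$intercept,
          slope = lf$slope, separation = lf$separation, auc = auc,
          n = lf$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, phenotype = phenotype, alpha = alpha,
            class = c("association_result", "data.frame"))
}

#' @export
print.association_result <- function(x, ...) {
  if (!"associated" %in% names(x)) {
    print(as.data.frame(x))
    return(invisible(x))
  }
  cat(sprintf("association_result: phenotype '%s', %d rows (%d associated at alpha = %g)\n",
              attr(x, "phenotype"), nrow(x), sum(x$associated, na.rm = TRUE),
              attr(x, "alpha")))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
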