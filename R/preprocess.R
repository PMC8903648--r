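#' Log2-transform an expression matrix
#'
#' Replaces every present value by its base-2 logarithm and sets the
#' `log2_transformed` flag. Raw intensities must be strictly positive;
#' a matrix already flagged as log2 is refused (double transform).
#'
#' @param m An [expression_matrix()] of raw (linear-scale) intensities.
#' @return The log2-scale `expr_matrix`; missingness is unchanged.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is_log2(m))
    stop("matrix is already log2-transformed (refusing a double transform)")
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive value ", m[bad[1, 1], bad[1, 2]], " at sample '",
         rownames(m)[bad[1, 1]], "', feature '", colnames(m)[bad[1, 2]],
         "'; log2 transform requires positive intensities")
  out <- log2(unclass(m))
  expression_matrix(out, log2_transformed = TRUE)
}

#' Median-normalize samples
#'
#' Additively shifts each sample so that the median over its present
#' feature values equals `target` (default 0), the usual alignment step for
#' log2-scale abundance matrices to damp sample-loading and batch effects.
#' The even-count median is the mean of the two central order statistics.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param target Real; the per-sample median after normalization.
#' @return The normalized `expr_matrix`.
#' @export
median_normalize <- function(m, target = 0) {
  stopifnot(inherits(m, "expr_matrix"))
  n_present <- rowSums(!is.na(m))
  if (any(n_present == 0))
    stop("sample(s) with no present values: ",
         paste(rownames(m)[n_present == 0], collapse = ", "))
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  out <- unclass(m) - med + target
  expression_matrix(out, log2_transformed = is_log2(m))
}

#' Remove noise features by observed fraction
#'
#' A feature quantified in too few samples carries more missingness
#' artifact than signal. Features are kept iff their observed fraction
#' (present values / sample count) is at least `min_observed_fraction`
#' (default 0.5, i.e. a feature present in exactly half the samples
#' survives).
#'
#' @param m An [expression_matrix()].
#' @param min_observed_fraction Real in \[0, 1\].
#' @return List with `matrix` (retained features, same samples) and
#'   `removed` (character vector of dropped feature ids).
#' @export
filter_noise_features <- function(m, min_observed_fraction = 0.5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (min_observed_fraction < 0 || min_observed_fraction > 1)
    stop("'min_observed_fraction' must be in [0, 1]")
  frac <- colSums(!is.na(m)) / nrow(m)
  keep <- frac >= min_observed_fraction
  list(matrix = m[, keep, drop = FALSE],
       removed = colnames(m)[!keep])
}

#' Impute missing values with scaled minima
#'
#' Minimum-value imputation for left-censored missingness: a missing entry
#' is assumed below the detection range and filled with a scaled minimum.
#' `global_min` uses the minimum over all present entries; `sample_min` the
#' minimum of the sample's (row's) present entries; `feature_min` the
#' minimum of the feature's (column's) present entries across samples.
#' Present values are never altered; `method = "none"` is the identity.
#'
#' @param m An [expression_matrix()].
#' @param method One of `"global_min"`, `"sample_min"`, `"feature_min"`,
#'   `"none"`.
#' @param scale Positive multiplier applied to the minimum (default 1).
#' @return An `expr_matrix` with no missing entries (unless
#'   `method = "none"`).
#' @export
impute_missing <- function(m, method = c("global_min", "sample_min",
                                         "feature_min", "none"),
                           scale = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("'scale' must be a positive number")
  if (method == "none") return(m)
  out <- unclass(m)
  miss <- is.na(out)
  if (!any(miss)) return(m)
  if (method == "global_min") {
    if (all(miss)) stop("cannot impute: matrix has no present values")
    out[miss] <- scale * min(out, na.rm = TRUE)
  } else if (method == "sample_min") {
    empty <- rowSums(!miss) == 0
    if (any(empty))
      stop("sample_min imputation on all-missing sample(s): ",
           paste(rownames(m)[empty], collapse = ", "), " (filter first)")
    mins <- apply(out, 1, min, na.rm = TRUE)
    fill <- matrix(scale * mins, nrow(out), ncol(out))
    out[miss] <- fill[miss]
  } else {
    empty <- colSums(!miss) == 0
    if (any(empty))
      stop("feature_min imputation on all-missing feature(s): ",
           paste(colnames(m)[empty], collapse = ", "), " (filter first)")
    mins <- apply(out, 2, min, na.rm = TRUE)
    fill <- matrix(scale * mins, nrow(out), ncol(out), byrow = TRUE)
    out[miss] <- fill[miss]
  }
  expression_matrix(out, log2_transformed = is_log2(m))
}

#' Replicate-based quality-control report
#'
#' Reproducibility metrics over designated quality-control samples
#' (technical or biological replicates): pairwise correlation of replicate
#' profiles, and the per-feature coefficient of variation (CV) across the
#' replicates.
#'
#' Correlations are computed per pair over the features present in both
#' samples; a pair sharing fewer than 3 features gets an undefined (`NA`)
#' correlation and is excluded from the mean. The CV is computed on the
#' linear scale (`2^value` when the matrix is log2; `cv_scale = "log2"`
#' computes it on the stored values instead) as the sample (n-1) standard
#' deviation over the mean; features with fewer than 2 present replicate
#' values get an undefined CV, and `median_cv` is the median of the finite
#' CVs.
#'
#' @param m An [expression_matrix()].
#' @param qc_sample_ids Character vector (length >= 2) of replicate sample
#'   ids present in `m`.
#' @param method Correlation flavor, `"pearson"` (default) or
#'   `"spearman"`.
#' @param cv_scale `"linear"` (default: CV of `2^value`) or `"log2"`.
#' @return An object of class `qc_report`: list with `correlations`
#'   (symmetric matrix, unit diagonal), `mean_correlation`, `cv`
#'   (data.frame feature/cv), `median_cv`, `qc_sample_ids`.
#' @export
qc_replicate_report <- function(m, qc_sample_ids,
                                method = c("pearson", "spearman"),
                                cv_scale = c("linear", "log2")) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  cv_scale <- match.arg(cv_scale)
  unknown <- setdiff(qc_sample_ids, rownames(m))
  if (length(unknown))
    stop("unknown QC sample id(s): ", paste(unknown, collapse = ", "))
  if (length(qc_sample_ids) < 2)
    stop("need at least 2 QC samples")
  sub <- unclass(m)[qc_sample_ids, , drop = FALSE]
  k <- length(qc_sample_ids)
  r <- diag(1, k)
  dimnames(r) <- list(qc_sample_ids, qc_sample_ids)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    ok <- !is.na(sub[i, ]) & !is.na(sub[j, ])
    r[i, j] <- r[j, i] <-
      if (sum(ok) < 3) NA_real_
      else stats::cor(sub[i, ok], sub[j, ok], method = method)
  }
  upper <- r[upper.tri(r)]
  mean_r <- if (all(is.na(upper))) NA_real_ else mean(upper, na.rm = TRUE)
  lin <- if (cv_scale == "linear" && is_log2(m)) 2^sub else sub
  cv <- apply(lin, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) NA_real_
    else stats::sd(x) / mean(x)
  })
  finite_cv <- cv[is.finite(cv)]
  structure(list(correlations = r,
                 mean_correlation = mean_r,
                 cv = data.frame(feature = colnames(m), cv = unname(cv),
                                 stringsAsFactors = FALSE),
                 median_cv = if (length(finite_cv)) stats::median(finite_cv)
                             else NA_real_,
                 qc_sample_ids = qc_sample_ids),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d QC samples, mean replicate r = %s, median CV = %s\n",
              length(x$qc_sample_ids),
              format(x$mean_correlation, digits = 3),
              format(x$median_cv, digits = 3)))
  invisible(x)
}
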