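#' Specification for a synthetic two-group omics cohort
#'
#' Describes a tumor/non-tumor style cohort with planted differential
#' features, the statistical structure the pipeline assumes: log2
#' abundances with feature baselines drawn Uniform(18, 30) (mimicking
#' reporter-intensity magnitudes), a planted group shift on a fraction of
#' features, Gaussian residual noise, completely-at-random (or
#' left-censored) missingness, optional technical-replicate QC samples,
#' and optional glycoform-style feature naming.
#'
#' @param n_per_group Samples per phenotype level (default 20).
#' @param n_features Number of features (default 1000).
#' @param frac_de Fraction of features carrying a planted group effect
#'   (default 0.1).
#' @param effect_log2fc Planted absolute log2 fold change (default 1).
#' @param noise_sd Residual standard deviation on the log2 scale
#'   (default 0.25).
#' @param missing_rate Fraction of entries set missing (default 0).
#' @param missing_mode `"mcar"` (default) or `"censored"` (the lowest
#'   values go missing, exercising minimum-value imputation).
#' @param n_qc_replicates Number of technical-replicate QC samples, noisy
#'   copies of the first sample (default 0).
#' @param glyco_mode Name features as valid glycoform identifiers.
#' @param seed Integer seed fixing every random draw.
#' @return Object of class `fixture_spec` (validated list).
#' @export
fixture_spec <- function(n_per_group = 20, n_features = 1000,
                         frac_de = 0.1, effect_log2fc = 1,
                         noise_sd = 0.25, missing_rate = 0,
                         missing_mode = c("mcar", "censored"),
                         n_qc_replicates = 0, glyco_mode = FALSE,
                         seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_per_group >= 2, n_features >= 1,
            frac_de >= 0, frac_de <= 1,
            missing_rate >= 0, missing_rate <= 1,
            noise_sd > 0, effect_log2fc >= 0,
            n_qc_replicates >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_features = as.integer(n_features),
                 frac_de = frac_de, effect_log2fc = effect_log2fc,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 missing_mode = missing_mode,
                 n_qc_replicates = as.integer(n_qc_replicates),
                 glyco_mode = isTRUE(glyco_mode),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.random_glycoform_ids <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  monos <- c("N", "H", "F", "S", "G")
  vapply(seq_len(n), function(i) {
    gene <- sprintf("GENE%d", i)
    len <- sample(6:14, 1)
    pep <- paste(sample(aa, len, replace = TRUE), collapse = "")
    start <- sample(2:900, 1)
    pos <- start + sample.int(len, 1) - 1L
    n_mono <- sample(2:4, 1)
    glycan <- paste0(sample(monos, n_mono), sample(1:9, n_mono, replace = TRUE),
                     collapse = "")
    paste(gene, start, pep, 1L, pos, glycan, sep = "_")
  }, "")
}

#' Generate a synthetic cohort
#'
#' Materializes the cohort a [fixture_spec()] describes. Log2 values are
#' `baseline(feature) + group * effect * direction(feature) + N(0,
#' noise_sd)`, where the effect applies only to the planted differential
#' features (random up/down direction, applied to the Tumor group). The
#' phenotype table carries a binary `Pathological_Status` (Tumor /
#' Non-Tumor) and a `Grade` numerical phenotype correlated with it
#' (non-tumors grade 1-2, tumors 2-3). QC replicate samples (ids `QC_1`,
#' ...) are noisy copies of the first sample and share its phenotype row.
#' The same seed reproduces the output bit for bit.
#'
#' @param spec A [fixture_spec()].
#' @return List with `matrix` (an [expression_matrix()]), `phenotypes`
#'   (a [phenotype_table()]), `truth` (data.frame `feature`, `is_de`,
#'   `direction`, `true_log2fc`) and `qc_sample_ids`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- 2L * spec$n_per_group
  p <- spec$n_features
  group <- rep(c(0L, 1L), each = spec$n_per_group)   # 0 = Non-Tumor, 1 = Tumor
  samples <- sprintf("S%03d", seq_len(n))
  features <- if (spec$glyco_mode) .random_glycoform_ids(p)
              else sprintf("GENE%d", seq_len(p))

  n_de <- round(spec$frac_de * p)
  de_idx <- if (n_de > 0) sort(sample.int(p, n_de)) else integer(0)
  direction <- rep(0L, p)
  if (n_de > 0) direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)

  baseline <- stats::runif(p, 18, 30)
  X <- matrix(baseline, n, p, byrow = TRUE) +
    outer(group, direction * spec$effect_log2fc) +
    matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
  dimnames(X) <- list(samples, features)

  if (spec$n_qc_replicates > 0) {
    qc_ids <- sprintf("QC_%d", seq_len(spec$n_qc_replicates))
    qc <- matrix(rep(X[1, ], spec$n_qc_replicates),
                 spec$n_qc_replicates, p, byrow = TRUE) +
      matrix(stats::rnorm(spec$n_qc_replicates * p, 0, spec$noise_sd),
             spec$n_qc_replicates, p)
    rownames(qc) <- qc_ids
    colnames(qc) <- features
    X <- rbind(X, qc)
  } else {
    qc_ids <- character(0)
  }

  if (spec$missing_rate > 0) {
    if (spec$missing_mode == "mcar") {
      miss <- stats::runif(length(X)) < spec$missing_rate
    } else {
      # left-censored: the lowest fraction of values goes missing
      cut <- stats::quantile(X, spec$missing_rate)
      miss <- X <= cut
    }
    X[miss] <- NA_real_
  }

  status <- c(ifelse(group == 1, "Tumor", "Non-Tumor"),
              rep(ifelse(group[1] == 1, "Tumor", "Non-Tumor"),
                  length(qc_ids)))
  grade <- ifelse(status == "Tumor",
                  sample(2:3, length(status), replace = TRUE),
                  sample(1:2, length(status), replace = TRUE))
  pheno <- phenotype_table(
    data.frame(Pathological_Status = status, Grade = as.numeric(grade),
               row.names = c(samples, qc_ids), stringsAsFactors = FALSE),
    kinds = c(Pathological_Status = "categorical", Grade = "numerical"))

  truth <- data.frame(
    feature = features,
    is_de = direction != 0L,
    direction = c("down", "ns", "up")[direction + 2L],
    true_log2fc = direction * spec$effect_log2fc,
    stringsAsFactors = FALSE)

  list(matrix = expression_matrix(X, log2_transformed = TRUE),
       phenotypes = pheno, truth = truth, qc_sample_ids = qc_ids)
}

#' Generate a toy GMT collection with one planted set
#'
#' Builds a small gene-set collection for end-to-end testing: one set is
#' the planted subset (e.g. the ground-truth differential genes) plus a
#' few random decoys, the remaining sets are random draws from the gene
#' universe. Deterministic by seed.
#'
#' @param genes Gene universe (character vector).
#' @param n_sets Number of sets in the collection (>= 1).
#' @param planted_set Subset of `genes` forming the planted set.
#' @param seed Integer seed.
#' @param path Optional output path; when given the collection is also
#'   written as a GMT file.
#' @param n_decoys Random decoy genes appended to the planted set
#'   (default 3).
#' @return A [gene_set_collection()] (invisibly carrying `path` when
#'   written). The planted set is named `"PLANTED_SET"`.
#' @export
generate_toy_gmt <- function(genes, n_sets, planted_set, seed = 1L,
                             path = NULL, n_decoys = 3) {
  stopifnot(n_sets >= 1)
  genes <- unique(as.character(genes))
  planted_set <- unique(as.character(planted_set))
  if (!all(planted_set %in% genes))
    stop("planted_set must be a subset of the gene universe")
  set.seed(seed)
  decoy_pool <- setdiff(genes, planted_set)
  sets <- list(PLANTED_SET = c(planted_set,
                               sample(decoy_pool,
                                      min(n_decoys, length(decoy_pool)))))
  if (n_sets > 1) {
    for (i in seq_len(n_sets - 1)) {
      size <- sample(5:max(5, min(50, length(genes))), 1)
      sets[[sprintf("RANDOM_SET_%d", i)]] <-
        sample(genes, min(size, length(genes)))
    }
  }
  coll <- gene_set_collection(
    sets,
    descriptions = stats::setNames(rep("synthetic", length(sets)),
                                   names(sets)),
    name = "toy_collection")
  if (!is.null(path)) write_gmt(coll, path)
  invisible(coll)
}
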