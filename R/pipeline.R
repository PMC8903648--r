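#' Pipeline configuration
#'
#' Collects every setting of the one-click run. Defaults equal the
#' conventional gates of the workflow: median normalization target 0,
#' 50% noise filter, fold-change gate 1.5, adjusted-p gate 0.01, top 100
#' PCA contributors, correlation alpha 0.05.
#'
#' @param matrix_path Path to the wide-format expression matrix.
#' @param phenotype_path Path to the tagged phenotype table.
#' @param out_dir Output directory (created if absent).
#' @param group_phenotype Categorical phenotype defining the comparison
#'   (default `"Pathological_Status"`).
#' @param group_levels Length-2 character vector `c(group1, group2)`;
#'   `NULL` (default) takes the two sorted levels as
#'   `c(level2, level1)`, i.e. the lexicographically later level (for
#'   Tumor / Non-Tumor: Tumor) is group 1, whose higher expression is
#'   reported "up".
#' @param log2_input Whether the matrix file already holds log2 values
#'   (default `TRUE`; `FALSE` log2-transforms after reading).
#' @param normalize_target Per-sample median after normalization;
#'   `NULL` skips normalization.
#' @param min_observed_fraction Noise-filter threshold (default 0.5).
#' @param imputation_method Passed to [impute_missing()]
#'   (default `"global_min"`).
#' @param imputation_scale Passed to [impute_missing()] (default 1).
#' @param qc_sample_ids Replicate sample ids for the QC report (optional).
#' @param annotation_db Optional [annotation_db()] for the annotation
#'   stage.
#' @param annotation_mode `"gene"` or `"glycosite"`.
#' @param de_test Test for [differential_expression()]
#'   (default `"student_t"`).
#' @param fc_threshold,adj_p_threshold Significance gates (1.5, 0.01).
#' @param paired_by Pairing phenotype for paired tests.
#' @param n_components,top_k PCA settings (defaults 10, 100).
#' @param cluster_k Flat cluster count (default 4).
#' @param association_alpha Correlation significance level (0.05).
#' @param associate_all Associate every feature instead of the
#'   selected union of DE calls, PCA top contributors and cluster sets.
#' @param gmt_path Optional GMT file for enrichment.
#' @param ora_min_size,ora_max_size ORA set-size bounds (5, 2000).
#' @param seed Integer seed recorded in the manifest and applied at run
#'   start.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("profile", "preprocess", "annotate", "discover", "associate",
#'   "enrich")`.
#' @param allow_subset Operate on the intersection of matrix and
#'   phenotype samples instead of requiring them to match exactly.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path, phenotype_path, out_dir,
                            group_phenotype = "Pathological_Status",
                            group_levels = NULL,
                            log2_input = TRUE,
                            normalize_target = 0,
                            min_observed_fraction = 0.5,
                            imputation_method = "global_min",
                            imputation_scale = 1,
                            qc_sample_ids = NULL,
                            annotation_db = NULL,
                            annotation_mode = "gene",
                            de_test = "student_t",
                            fc_threshold = 1.5,
                            adj_p_threshold = 0.01,
                            paired_by = NULL,
                            n_components = 10, top_k = 100,
                            cluster_k = 4,
                            association_alpha = 0.05,
                            associate_all = FALSE,
                            gmt_path = NULL,
                            ora_min_size = 5, ora_max_size = 2000,
                            seed = 1L,
                            stages = c("profile", "preprocess", "annotate",
                                       "discover", "associate", "enrich"),
                            allow_subset = FALSE) {
  for (pth in c(matrix_path, phenotype_path, gmt_path))
    if (!is.null(pth) && !file.exists(pth)) stop("file not found: ", pth)
  known <- c("profile", "preprocess", "annotate", "discover", "associate",
             "enrich")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment())[setdiff(names(formals()), "known")],
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value file
#'
#' A plain human-readable `key = value` (or `key: value`) text file, one
#' setting per line, `#` comments allowed. Keys match the arguments of
#' [pipeline_config()]; list-valued keys (`stages`, `group_levels`,
#' `qc_sample_ids`) take comma-separated values.
#'
#' @param path Config file path.
#' @param ... Overrides passed straight to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("unparseable config line: ", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  args <- list()
  num_keys <- c("normalize_target", "min_observed_fraction",
                "imputation_scale", "fc_threshold", "adj_p_threshold",
                "n_components", "top_k", "cluster_k", "association_alpha",
                "ora_min_size", "ora_max_size", "seed")
  lgl_keys <- c("log2_input", "associate_all", "allow_subset")
  lst_keys <- c("stages", "group_levels", "qc_sample_ids")
  for (key in names(kv)) {
    val <- kv[[key]]
    args[[key]] <-
      if (key %in% num_keys) as.numeric(val)
      else if (key %in% lgl_keys) toupper(val) %in% c("TRUE", "YES", "1")
      else if (key %in% lst_keys) trimws(strsplit(val, ",")[[1]])
      else val
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

.write_stage_csv <- function(df, out_dir, file, manifest) {
  path <- file.path(out_dir, file)
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  manifest$outputs[[file]] <- nrow(as.data.frame(df))
  manifest
}

#' Run the one-click pipeline
#'
#' Executes the enabled stages in workflow order — phenotype profiling,
#' preprocessing and QC, knowledge annotation, feature discovery
#' (differential expression, PCA contribution ranking, clustering),
#' per-feature association, enrichment — each writing its CSV result
#' table before the next starts. Stages whose optional inputs are absent
#' (no QC sample ids, no annotation database, no GMT file) are skipped
#' with a logged warning rather than failing the run. Identical config,
#' inputs and seed produce byte-identical outputs.
#'
#' Output files (in `cfg$out_dir`): `phenotype_profile.csv`,
#' `phenotype_correlation.csv`, `qc_report.csv`, `preprocessed_matrix.csv`,
#' `annotations.csv`, `de_results.csv`, `pca_contributions.csv`,
#' `pca_variance_ratio.csv`, `pca_top_per_component.csv`, `clusters.csv`,
#' `associations.csv`, `enrichment.csv`, and `manifest.json`.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The run manifest (list: config snapshot, package version,
#'   per-output row counts, warnings, timing), invisibly. Also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  set.seed(cfg$seed)
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenolink")),
    seed = cfg$seed,
    stages_enabled = cfg$stages,
    outputs = list(), warnings = character(0), stages_completed = character(0))
  note <- function(msg) {
    manifest$warnings <<- c(manifest$warnings, msg)
    say("note: ", msg)
  }

  m <- read_expression_matrix(cfg$matrix_path,
                              log2_transformed = cfg$log2_input)
  ph <- read_phenotype_table(cfg$phenotype_path)
  only_m <- setdiff(rownames(m), rownames(ph))
  only_p <- setdiff(rownames(ph), rownames(m))
  if (length(only_m) || length(only_p)) {
    if (!cfg$allow_subset)
      stop("sample-name mismatch between matrix and phenotype table; ",
           "matrix-only: {", paste(only_m, collapse = ", "),
           "}, phenotype-only: {", paste(only_p, collapse = ", "), "}")
    shared <- intersect(rownames(m), rownames(ph))
    if (!length(shared)) stop("no shared samples")
    m <- m[shared, , drop = FALSE]
    ph <- phenotype_table(as.data.frame(ph)[shared, , drop = FALSE],
                          phenotype_kinds(ph))
    note(sprintf("subset to %d shared samples", length(shared)))
  }
  manifest$n_samples <- nrow(m)
  manifest$n_features_input <- ncol(m)

  ## -- profile ------------------------------------------------------------
  if ("profile" %in% cfg$stages) {
    say("stage: profile")
    manifest <- .write_stage_csv(profile_phenotypes(ph), cfg$out_dir,
                                 "phenotype_profile.csv", manifest)
    if (ncol(ph) >= 2) {
      pc <- correlate_phenotypes(ph)
      long <- expand.grid(phenotype_1 = rownames(pc$r),
                          phenotype_2 = colnames(pc$r),
                          stringsAsFactors = FALSE)
      long$r <- as.vector(pc$r)
      long$p_value <- as.vector(pc$p_value)
      manifest <- .write_stage_csv(long, cfg$out_dir,
                                   "phenotype_correlation.csv", manifest)
    } else {
      note("phenotype correlation skipped: fewer than 2 phenotypes")
    }
    manifest$stages_completed <- c(manifest$stages_completed, "profile")
  }

  ## -- preprocess / QC ----------------------------------------------------
  if ("preprocess" %in% cfg$stages) {
    say("stage: preprocess")
    if (!is_log2(m)) m <- log2_transform(m)
    if (!is.null(cfg$normalize_target))
      m <- median_normalize(m, cfg$normalize_target)
    flt <- filter_noise_features(m, cfg$min_observed_fraction)
    m <- flt$matrix
    manifest$n_features_removed <- length(flt$removed)
    if (length(flt$removed))
      note(sprintf("noise filter removed %d feature(s)", length(flt$removed)))
    n_miss <- sum(is.na(m))
    if (cfg$imputation_method != "none" && n_miss > 0) {
      m <- impute_missing(m, cfg$imputation_method, cfg$imputation_scale)
      note(sprintf("imputed %d missing value(s) by %s", n_miss,
                   cfg$imputation_method))
    }
    if (!is.null(cfg$qc_sample_ids) && length(cfg$qc_sample_ids) >= 2) {
      qc <- qc_replicate_report(m, cfg$qc_sample_ids)
      pairs <- which(upper.tri(qc$correlations), arr.ind = TRUE)
      qc_long <- rbind(
        data.frame(metric = "replicate_r",
                   item = paste(rownames(qc$correlations)[pairs[, 1]],
                                colnames(qc$correlations)[pairs[, 2]],
                                sep = "|"),
                   value = qc$correlations[pairs],
                   stringsAsFactors = FALSE),
        data.frame(metric = "mean_correlation", item = "",
                   value = qc$mean_correlation, stringsAsFactors = FALSE),
        data.frame(metric = "cv", item = qc$cv$feature, value = qc$cv$cv,
                   stringsAsFactors = FALSE),
        data.frame(metric = "median_cv", item = "", value = qc$median_cv,
                   stringsAsFactors = FALSE))
      manifest <- .write_stage_csv(qc_long, cfg$out_dir, "qc_report.csv",
                                   manifest)
    } else {
      note("QC report skipped: no (or <2) QC sample ids configured")
    }
    # QC samples are technical replicates, not cohort members: once the QC
    # report is written they are excluded from the association stages.
    qc_present <- intersect(cfg$qc_sample_ids, rownames(m))
    if (length(qc_present)) {
      keep <- setdiff(rownames(m), qc_present)
      m <- m[keep, , drop = FALSE]
      ph <- phenotype_table(as.data.frame(ph)[keep, , drop = FALSE],
                            phenotype_kinds(ph))
      note(sprintf("%d QC sample(s) excluded from downstream analysis",
                   length(qc_present)))
    }
    write_expression_matrix(m, file.path(cfg$out_dir,
                                         "preprocessed_matrix.csv"))
    manifest$outputs[["preprocessed_matrix.csv"]] <- nrow(m)
    manifest$stages_completed <- c(manifest$stages_completed, "preprocess")
  }

  ## -- annotate -----------------------------------------------------------
  if ("annotate" %in% cfg$stages) {
    if (!is.null(cfg$annotation_db)) {
      say("stage: annotate")
      ann <- annotate_features(colnames(m), cfg$annotation_db,
                               mode = cfg$annotation_mode)
      manifest <- .write_stage_csv(ann, cfg$out_dir, "annotations.csv",
                                   manifest)
      manifest$stages_completed <- c(manifest$stages_completed, "annotate")
    } else {
      note("annotation skipped: no annotation database configured")
    }
  }

  ## -- discover -----------------------------------------------------------
  selected <- character(0)
  if ("discover" %in% cfg$stages) {
    say("stage: discover")
    lev <- cfg$group_levels
    if (is.null(lev)) {
      found <- sort(unique(stats::na.omit(ph[[cfg$group_phenotype]])))
      if (length(found) != 2)
        stop("group_levels not given and phenotype '", cfg$group_phenotype,
             "' has ", length(found), " levels")
      lev <- c(found[2], found[1])
    }
    de <- differential_expression(
      m, ph, cfg$group_phenotype, lev[1], lev[2],
      test = cfg$de_test, fc_threshold = cfg$fc_threshold,
      adj_p_threshold = cfg$adj_p_threshold, paired_by = cfg$paired_by)
    manifest <- .write_stage_csv(de, cfg$out_dir, "de_results.csv", manifest)

    dm <- m
    if (anyNA(dm)) dm <- impute_missing(dm, "global_min")
    pca <- pca_contribution(dm, n_components = cfg$n_components,
                            top_k = cfg$top_k)
    manifest <- .write_stage_csv(
      pca$contribution[order(-pca$contribution$score), ],
      cfg$out_dir, "pca_contributions.csv", manifest)
    manifest <- .write_stage_csv(
      data.frame(component = seq_along(pca$explained_variance_ratio),
                 variance_ratio = pca$explained_variance_ratio),
      cfg$out_dir, "pca_variance_ratio.csv", manifest)
    manifest <- .write_stage_csv(
      data.frame(component = rep(names(pca$top_per_component),
                                 vapply(pca$top_per_component, length, 0L)),
                 rank = unlist(lapply(pca$top_per_component, seq_along)),
                 feature = unlist(pca$top_per_component)),
      cfg$out_dir, "pca_top_per_component.csv", manifest)

    sds <- apply(unclass(dm), 2, stats::sd)
    cm <- if (any(sds == 0)) dm[, sds > 0, drop = FALSE] else dm
    if (any(sds == 0))
      note(sprintf("%d constant feature(s) excluded from clustering",
                   sum(sds == 0)))
    cl <- cluster_features(cm, k = min(cfg$cluster_k, ncol(cm)))
    manifest <- .write_stage_csv(
      data.frame(feature = names(cl$assignments),
                 cluster = unname(cl$assignments)),
      cfg$out_dir, "clusters.csv", manifest)

    selected <- unique(c(de$feature[de$direction != "ns"], pca$top_features))
    manifest$stages_completed <- c(manifest$stages_completed, "discover")
  }

  ## -- associate ----------------------------------------------------------
  if ("associate" %in% cfg$stages) {
    say("stage: associate")
    feats <- if (cfg$associate_all || !length(selected)) NULL else selected
    assoc <- associate_features(m, ph, cfg$group_phenotype,
                                features = feats,
                                alpha = cfg$association_alpha)
    manifest <- .write_stage_csv(assoc, cfg$out_dir, "associations.csv",
                                 manifest)
    manifest$stages_completed <- c(manifest$stages_completed, "associate")
  }

  ## -- enrich -------------------------------------------------------------
  if ("enrich" %in% cfg$stages) {
    if (is.null(cfg$gmt_path)) {
      note("enrichment skipped: no GMT file configured")
    } else if (!("discover" %in% cfg$stages) ||
               !any(length(selected))) {
      note("enrichment skipped: no selected features from discovery")
    } else {
      say("stage: enrich")
      coll <- read_gmt(cfg$gmt_path)
      de_path <- file.path(cfg$out_dir, "de_results.csv")
      de_tab <- utils::read.csv(de_path, stringsAsFactors = FALSE)
      query <- features_to_genes(de_tab$feature[de_tab$direction != "ns"])
      if (!length(query)) {
        note("enrichment skipped: no significant features")
      } else {
        enr <- ora(query, features_to_genes(colnames(m)), coll,
                   min_size = cfg$ora_min_size, max_size = cfg$ora_max_size)
        manifest <- .write_stage_csv(enr, cfg$out_dir, "enrichment.csv",
                                     manifest)
        manifest$stages_completed <- c(manifest$stages_completed, "enrich")
      }
    }
  }

  manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "elapsed_seconds")],
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  say(sprintf("pipeline finished in %.1f s; %d output file(s)",
              manifest$elapsed_seconds, length(manifest$outputs)))
  invisible(manifest)
}
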