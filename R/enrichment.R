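#' Read a GMT gene-set collection
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member case is
#' preserved; duplicate members within a set are deduplicated; a duplicate
#' set name or a line with fewer than 3 fields is an error.
#'
#' @param path GMT file path.
#' @param name Collection name (defaults to the file base name).
#' @return Object of class `gene_set_collection`: list with `name`,
#'   `sets` (named list of character vectors), `descriptions`, `source`.
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               name = name %||% basename(path),
                               source = path))
  }
  sets <- list(); descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has ", length(fields),
           " field(s); need name, description and >= 1 member")
    nm <- trimws(fields[1])
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- unique(trimws(fields[-(1:2)]))
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    descriptions[nm] <- fields[2]
  }
  gene_set_collection(sets, descriptions = descriptions,
                      name = name %||% basename(path), source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_gmt
#' @param sets Named list of member character vectors.
#' @param descriptions Optional named character vector of set
#'   descriptions.
#' @param source Provenance string.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                name = "collection", source = NA_character_) {
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(name = name, sets = sets,
                 descriptions = descriptions, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, 0L)
  cat(sprintf("gene_set_collection '%s': %d sets (sizes %s)\n",
              x$name, length(x$sets),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$descriptions[nm]
    if (is.null(desc) || is.na(desc)) desc <- "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Collapse feature identifiers to gene symbols
#'
#' Glycoform identifiers collapse to their gene-symbol field; plain gene
#' identifiers pass through; the result is deduplicated preserving first
#' occurrence, which is how glycopeptide-level selections become gene
#' lists for enrichment.
#'
#' @param features Character vector of feature identifiers.
#' @return Character vector of unique gene symbols.
#' @export
features_to_genes <- function(features) {
  genes <- vapply(as.character(features), function(f) {
    parsed <- try(.parse_one_glycoform(f), silent = TRUE)
    if (inherits(parsed, "try-error")) f else parsed$gene
  }, "", USE.NAMES = FALSE)
  unique(genes)
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected under random sampling from the background universe
#' (conventionally the genes measured in the input matrix, not the
#' genome). With background size `N`, background-restricted set size `K`,
#' query size `n` and overlap `k`, the enrichment p-value is the
#' hypergeometric upper tail `P(X >= k)` (so `k = 0` gives p = 1). Sets
#' are size-filtered after background restriction (`K` in
#' `[min_size, max_size]`, and `K < N`); p-values are BH-adjusted across
#' all tested sets and rows are sorted by adjusted then raw p-value.
#'
#' Query symbols absent from the background are dropped with a warning:
#' a selection can only be enriched relative to the universe it was
#' selected from.
#'
#' @param query Character vector of selected gene symbols.
#' @param background Character vector: the measured gene universe.
#' @param collection A [gene_set_collection()].
#' @param min_size,max_size Background-restricted set-size bounds
#'   (defaults 5 and 2000).
#' @return Object of class `enrichment_result`: data.frame with columns
#'   `set`, `overlap_k`, `set_size_K`, `query_n`, `background_N`,
#'   `p_value`, `adj_p`, `overlap_genes` (slash-separated).
#' @export
ora <- function(query, background, collection, min_size = 5,
                max_size = 2000) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!length(query)) stop("empty query gene list")
  if (!length(background)) stop("empty background gene list")
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) absent from background dropped: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "")
    query <- intersect(query, background)
    if (!length(query)) stop("no query gene remains inside the background")
  }
  N <- length(background); n <- length(query)
  rows <- list()
  for (nm in names(collection$sets)) {
    members <- intersect(collection$sets[[nm]], background)
    K <- length(members)
    if (K < min_size || K > max_size || K >= N) next
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(
      set = nm, overlap_k = k, set_size_K = K, query_n = n,
      background_N = N, p_value = p,
      overlap_genes = paste(sort(hits), collapse = "/"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(set = character(0), overlap_k = integer(0),
                      set_size_K = integer(0), query_n = integer(0),
                      background_N = integer(0), p_value = numeric(0),
                      adj_p = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_result", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- benjamini_hochberg(out$p_value)
  out <- out[order(out$adj_p, out$p_value, out$set), ]
  out <- out[, c("set", "overlap_k", "set_size_K", "query_n",
                 "background_N", "p_value", "adj_p", "overlap_genes")]
  rownames(out) <- NULL
  structure(out, collection = collection$name,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d sets tested against '%s'\n",
              nrow(x), attr(x, "collection") %||% "collection"))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
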