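#' Load a keyed annotation database
#'
#' Annotation databases are local TSV snapshots of knowledge resources (a
#' UniProtKB-style gene annotation table, or an N-glycosite atlas keyed on
#' gene plus glycosite position). The database declares its key column(s)
#' and an optional URL template whose `{column}` placeholders are filled
#' from the key fields of each matched feature to link out to the source
#' resource.
#'
#' @param path TSV file with a header row; must contain every key column.
#' @param key_columns Character vector of joining column names (e.g.
#'   `"gene"`, or `c("gene", "glycosite_position")`).
#' @param url_template Optional URL pattern with `{column}` placeholders,
#'   e.g. `"https://www.uniprot.org/uniprotkb?query={gene}"`.
#' @return An object of class `annotation_db`.
#' @export
read_annotation_db <- function(path, key_columns, url_template = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.table(path, sep = "\t", header = TRUE,
                               check.names = FALSE, quote = "\"",
                               comment.char = "", stringsAsFactors = FALSE,
                               colClasses = "character")
  annotation_db(records, key_columns, url_template)
}

#' @rdname read_annotation_db
#' @param records data.frame of annotation rows (all character).
#' @export
annotation_db <- function(records, key_columns, url_template = NULL) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  missing_keys <- setdiff(key_columns, names(records))
  if (nrow(records) == 0 && length(names(records)) == 0) {
    # empty database: synthesize the declared key columns
    records <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(key_columns)), key_columns),
      check.names = FALSE)
    missing_keys <- character(0)
  }
  if (length(missing_keys))
    stop("annotation database missing key column(s): ",
         paste(missing_keys, collapse = ", "))
  for (k in key_columns) {
    empty <- is.na(records[[k]]) | trimws(as.character(records[[k]])) == ""
    if (any(empty))
      stop("annotation database has ", sum(empty),
           " record(s) with an empty key field '", k, "'")
  }
  structure(list(records = records, key_columns = key_columns,
                 url_template = url_template),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation_db: %d records, keyed on (%s)%s\n",
              nrow(x$records), paste(x$key_columns, collapse = ", "),
              if (is.null(x$url_template)) "" else ", with URL template"))
  invisible(x)
}

.render_url <- function(template, fields) {
  url <- template
  for (nm in names(fields))
    url <- gsub(paste0("{", nm, "}"), fields[[nm]], url, fixed = TRUE)
  if (grepl("\\{[^}]*\\}", url))
    stop("URL template has unfilled placeholder(s): ", url)
  url
}

#' Annotate features against a knowledge database
#'
#' Left-joins a feature list against an [annotation_db()], preserving input
#' order: every input feature yields exactly one output row, with matched
#' rows carrying the database's annotation fields and a rendered URL, and
#' unmatched rows flagged `matched = FALSE` with empty annotation fields.
#'
#' In `"gene"` mode the feature identifier itself is the gene key (glycoform
#' identifiers are first collapsed to their gene symbol). In `"glycosite"`
#' mode feature identifiers must parse as glycoforms and the join key is
#' (gene, glycosite position), so two glycans at the same site share one
#' annotation row.
#'
#' @param features Character vector of feature identifiers.
#' @param db An [annotation_db()].
#' @param mode `"gene"` or `"glycosite"`.
#' @return data.frame: `feature`, key column(s), annotation fields,
#'   `matched`, and `url` when the database declares a template.
#' @export
annotate_features <- function(features, db, mode = c("gene", "glycosite")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "annotation_db"))
  if (mode == "glycosite") {
    need <- c("gene", "glycosite_position")
    if (!all(need %in% db$key_columns))
      stop("glycosite mode requires key columns (gene, glycosite_position)")
    parsed <- parse_glycoform(features)
    keys <- data.frame(gene = parsed$gene,
                       glycosite_position = as.character(parsed$glycosite_position),
                       stringsAsFactors = FALSE)
  } else {
    gene <- ifelse(is_glycoform(features),
                   vapply(features, function(f)
                     if (is_glycoform(f)) .parse_one_glycoform(f)$gene else f, ""),
                   features)
    keys <- data.frame(gene = as.character(gene), stringsAsFactors = FALSE)
  }
  keycols <- names(keys)
  db_key <- do.call(paste, c(lapply(keycols, function(k)
    as.character(db$records[[k]])), sep = "\r"))
  ft_key <- do.call(paste, c(unname(keys), sep = "\r"))
  hit <- match(ft_key, db_key)
  ann_cols <- setdiff(names(db$records), keycols)
  out <- data.frame(feature = features, keys, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (ac in ann_cols) {
    v <- as.character(db$records[[ac]])[hit]
    v[is.na(hit)] <- ""
    out[[ac]] <- v
  }
  out$matched <- !is.na(hit)
  if (!is.null(db$url_template)) {
    out$url <- vapply(seq_along(features), function(i) {
      if (is.na(hit[i])) return("")
      .render_url(db$url_template, as.list(keys[i, , drop = FALSE]))
    }, "")
  }
  rownames(out) <- NULL
  out
}
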