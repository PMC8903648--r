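#' Construct a phenotype table
#'
#' Per-sample clinical variables. Each phenotype is either categorical
#' (free-text levels) or numerical (finite reals); the kind is recorded per
#' column. Stored as a data.frame with sample identifiers as row names and a
#' `kinds` attribute (named character vector, values `"categorical"` or
#' `"numerical"`).
#'
#' @param data data.frame of per-sample values, samples in rows (row names
#'   required and unique). Categorical columns are character, numerical
#'   columns numeric; missing values are `NA`.
#' @param kinds Named character vector mapping each column of `data` to
#'   `"categorical"` or `"numerical"`.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(data, kinds) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame")
  if (is.null(rownames(data))) stop("phenotype table requires sample row names")
  dup <- rownames(data)[duplicated(rownames(data))]
  if (length(dup))
    stop("duplicate sample label(s): ", paste(unique(dup), collapse = ", "))
  if (!setequal(names(kinds), names(data)) || anyDuplicated(names(kinds)))
    stop("'kinds' must name every phenotype column exactly once")
  kinds <- kinds[names(data)]
  ok <- kinds %in% c("categorical", "numerical")
  if (!all(ok))
    stop("unrecognized phenotype kind(s): ",
         paste(unique(kinds[!ok]), collapse = ", "))
  for (nm in names(data)) {
    if (kinds[[nm]] == "numerical") {
      v <- data[[nm]]
      if (!is.numeric(v))
        stop("numerical phenotype '", nm, "' holds non-numeric values")
      if (any(!is.na(v) & !is.finite(v)))
        stop("numerical phenotype '", nm, "' holds non-finite values")
    } else {
      data[[nm]] <- as.character(data[[nm]])
    }
  }
  structure(data, kinds = kinds, class = c("phenotype_table", "data.frame"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  k <- phenotype_kinds(x)
  cat(sprintf("phenotype_table: %d samples, %d phenotypes (%d categorical, %d numerical)\n",
              nrow(x), ncol(x), sum(k == "categorical"), sum(k == "numerical")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @rdname phenotype_table
#' @param p A `phenotype_table`.
#' @export
phenotype_kinds <- function(p) attr(p, "kinds")

#' @rdname phenotype_table
#' @export
phenotype_names <- function(p) names(p)

.kind_tag_re <- "\\s*\\((Categorical|Numerical)\\)\\s*$"

#' Read a tagged phenotype table
#'
#' Reads a samples x phenotypes table in the same wide text layout as the
#' expression matrix. Every column label must carry a kind tag suffix,
#' `"(Categorical)"` or `"(Numerical)"`; the tag is stripped from the stored
#' phenotype name and recorded as the column kind. Numerical columns are
#' parsed as reals (a non-empty unparseable cell is an error); empty cells
#' and `NA`/`NaN` sentinels are missing in either kind.
#'
#' @inheritParams read_expression_matrix
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path, delimiter = NULL,
                                 na_tokens = .default_na_tokens) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .infer_delim(path, delimiter)
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("phenotype table needs at least one phenotype column")
  labels <- trimws(as.character(raw[1, -1]))
  untagged <- labels[!grepl(.kind_tag_re, labels)]
  if (length(untagged))
    stop("phenotype column(s) without a '(Categorical)'/'(Numerical)' tag: ",
         paste(untagged, collapse = ", "))
  kinds <- tolower(sub(paste0("^.*", .kind_tag_re), "\\1", labels))
  names_clean <- trimws(sub(.kind_tag_re, "", labels))
  samples <- trimws(as.character(raw[-1, 1]))
  out <- list()
  for (j in seq_along(names_clean)) {
    v <- trimws(as.character(raw[-1, j + 1]))
    miss <- tolower(v) %in% tolower(na_tokens)
    if (kinds[j] == "numerical") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!miss & is.na(num))
      if (length(bad))
        stop("numerical phenotype '", names_clean[j],
             "' has unparseable value '", v[bad[1]],
             "' for sample '", samples[bad[1]], "'")
      num[miss] <- NA_real_
      out[[j]] <- num
    } else {
      v[miss] <- NA_character_
      out[[j]] <- v
    }
  }
  names(out) <- names_clean
  df <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- samples
  phenotype_table(df, stats::setNames(kinds, names_clean))
}

#' Write a tagged phenotype table
#'
#' Inverse of [read_phenotype_table()]: re-attaches the kind tag to each
#' column label and writes missing values as empty cells.
#'
#' @param p A `phenotype_table`.
#' @param path Output path.
#' @param delimiter Field delimiter; `NULL` infers from extension.
#' @export
write_phenotype_table <- function(p, path, delimiter = NULL) {
  delim <- .infer_delim(path, delimiter)
  kinds <- phenotype_kinds(p)
  tags <- ifelse(kinds == "categorical", "(Categorical)", "(Numerical)")
  header <- paste(c("Sample", paste(names(p), tags)), collapse = delim)
  body <- vapply(seq_len(nrow(p)), function(i) {
    vals <- vapply(names(p), function(nm) {
      v <- p[[nm]][i]
      if (is.na(v)) "" else if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, "")
    paste(c(rownames(p)[i], vals), collapse = delim)
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
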