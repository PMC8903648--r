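#' Construct an expression matrix
#'
#' The central container of the package: a samples x features grid of
#' quantitative abundances (conventionally log2-transformed reporter
#' intensities), stored as a base numeric matrix with sample identifiers as
#' row names and feature identifiers (gene symbols or glycoform identifiers)
#' as column names. Missing quantifications are `NA`; every present entry
#' must be finite.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row
#'   and column names are required and must be unique.
#' @param log2_transformed Logical flag recording whether values are on the
#'   log2 scale. Most downstream operations require `TRUE`.
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `log2_transformed` attribute).
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 2, 3, 4), 2, 2,
#'          dimnames = list(c("S1", "S2"), c("ALB", "TF"))),
#'   log2_transformed = TRUE)
#' n_samples(m)
#' @export
expression_matrix <- function(values, log2_transformed = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires sample (row) and feature (column) names")
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s))
    stop("duplicate sample label(s): ", paste(unique(dup_s), collapse = ", "))
  dup_f <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_f))
    stop("duplicate feature label(s): ", paste(unique(dup_f), collapse = ", "))
  bad <- which(!is.na(values) & !is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value at sample '", rownames(values)[bad[1, 1]],
         "', feature '", colnames(values)[bad[1, 2]], "'")
  structure(values, log2_transformed = isTRUE(log2_transformed),
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d features (%slog2; %d missing)\n",
              nrow(x), ncol(x),
              if (is_log2(x)) "" else "not ",
              sum(is.na(x))))
  if (nrow(x) > 6 || ncol(x) > 6) {
    print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                     drop = FALSE])
    cat("...\n")
  } else {
    print(unclass(x))
  }
  invisible(x)
}

#' Subsetting keeps the class and log2 flag when the result is a matrix
#' @param x An `expr_matrix`.
#' @param i,j Row/column indices.
#' @param drop Passed through; when the result drops to a vector the class
#'   is dropped with it.
#' @param ... Ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, log2_transformed = attr(x, "log2_transformed"),
                     class = class(x))
  out
}

#' @rdname expression_matrix
#' @param m An `expr_matrix`.
#' @export
is_log2 <- function(m) isTRUE(attr(m, "log2_transformed"))

#' @rdname expression_matrix
#' @export
n_samples <- function(m) nrow(m)

#' @rdname expression_matrix
#' @export
n_features <- function(m) ncol(m)

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) rownames(m)

#' @rdname expression_matrix
#' @export
feature_ids <- function(m) colnames(m)

## delimiter from file extension: .csv -> comma, anything else -> tab
.infer_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.default_na_tokens <- c("", "NA", "NaN")

## Parse a character grid to numeric, mapping sentinel tokens to NA and
## raising a located error on anything else non-numeric.
.parse_numeric_grid <- function(cells, na_tokens, what = "matrix") {
  flat <- trimws(as.vector(cells))
  is_na <- tolower(flat) %in% tolower(na_tokens)
  num <- suppressWarnings(as.numeric(flat))
  bad <- which(!is_na & is.na(num))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(cells))
    stop(sprintf(
      "non-numeric cell '%s' in %s at row '%s', column '%s'",
      flat[bad[1]], what, rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  num[is_na] <- NA_real_
  matrix(num, nrow(cells), ncol(cells), dimnames = dimnames(cells))
}

#' Read a wide-format expression matrix
#'
#' Reads delimiter-separated text in "wide" layout: the first row is a header
#' of feature names, the first column holds sample names, and each remaining
#' cell is a quantitative abundance. Empty cells and the sentinel tokens
#' (default `""`, `"NA"`, `"NaN"`, case-insensitive) become missing values.
#' The delimiter is inferred from the file extension (`.csv` is
#' comma-separated, everything else tab-separated) unless given explicitly.
#'
#' @param path Path to the text file.
#' @param delimiter Field delimiter; `NULL` (default) infers from extension.
#' @param na_tokens Character vector of sentinel tokens treated as missing.
#' @param log2_transformed Whether the stored values are already on the log2
#'   scale (the conventional input, and the default).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, delimiter = NULL,
                                   na_tokens = .default_na_tokens,
                                   log2_transformed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .infer_delim(path, delimiter)
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 2)
    stop("matrix file needs a header row, a sample-id column and >=1 data cell")
  features <- trimws(as.character(raw[1, -1]))
  samples <- trimws(as.character(raw[-1, 1]))
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  dimnames(cells) <- list(samples, features)
  expression_matrix(.parse_numeric_grid(cells, na_tokens, "expression matrix"),
                    log2_transformed = log2_transformed)
}

#' Write a wide-format expression matrix
#'
#' Inverse of [read_expression_matrix()]: values are formatted with 17
#' significant digits so that a read-back reproduces every present value
#' exactly, and missing entries are written as empty cells.
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @param delimiter Field delimiter; `NULL` infers from extension.
#' @export
write_expression_matrix <- function(m, path, delimiter = NULL) {
  delim <- .infer_delim(path, delimiter)
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  txt[is.na(m)] <- ""
  lines <- c(paste(c("Sample", colnames(m)), collapse = delim),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], txt[i, ]), collapse = delim), ""))
  writeLines(lines, path)
  invisible(path)
}
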