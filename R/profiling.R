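#' Profile phenotype cohort composition
#'
#' First step of any association study: what does the cohort look like?
#' For each categorical phenotype, counts samples per level (plus the
#' missing count); for each numerical phenotype, reports n, mean, median,
#' min, max and the missing count over non-missing values.
#'
#' @param p A [phenotype_table()].
#' @return Long-format data.frame: `phenotype`, `kind`, `stat` (a level
#'   name, `"missing"`, or a summary-statistic name) and `value`.
#' @export
profile_phenotypes <- function(p) {
  stopifnot(inherits(p, "phenotype_table"))
  kinds <- phenotype_kinds(p)
  rows <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    if (kinds[[nm]] == "categorical") {
      lev <- sort(unique(v[!is.na(v)]))
      counts <- vapply(lev, function(l) sum(v == l, na.rm = TRUE), 0L)
      rows[[nm]] <- data.frame(
        phenotype = nm, kind = "categorical",
        stat = c(lev, "missing"),
        value = c(counts, sum(is.na(v))),
        stringsAsFactors = FALSE)
    } else {
      x <- v[!is.na(v)]
      vals <- if (length(x))
        c(n = length(x), mean = mean(x), median = stats::median(x),
          min = min(x), max = max(x), missing = sum(is.na(v)))
      else
        c(n = 0, mean = NA_real_, median = NA_real_, min = NA_real_,
          max = NA_real_, missing = sum(is.na(v)))
      rows[[nm]] <- data.frame(
        phenotype = nm, kind = "numerical",
        stat = names(vals), value = unname(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Encode a categorical phenotype numerically
#'
#' Maps the levels, sorted lexicographically, to 0, 1, 2, ...; missing
#' values stay missing. The encoding map is returned for auditability
#' (multi-level encodings are order-dependent, so downstream correlations
#' should be read as ordinal at best).
#'
#' @param values Character vector of per-sample categorical values.
#' @return List with `values` (numeric encoding) and `map` (named integer
#'   vector level -> code).
#' @export
encode_categorical <- function(values) {
  values <- as.character(values)
  lev <- sort(unique(values[!is.na(values)]))
  if (!length(lev)) stop("cannot encode: no non-missing level")
  map <- stats::setNames(seq_along(lev) - 1L, lev)
  list(values = as.numeric(map[values]), map = map)
}

#' Pairwise phenotype correlation
#'
#' Reveals dependencies between clinical variables (e.g. tumor stage vs
#' grade). Categorical phenotypes are first encoded numerically with
#' [encode_categorical()]; each pair is then correlated over the samples
#' non-missing in both. Spearman rank correlation is the default since the
#' encodings are ordinal at best. Pairs with a constant vector or fewer
#' than 3 shared samples get an undefined correlation (reported as `NA`,
#' not fabricated). P-values use the t-approximation of the chosen
#' correlation.
#'
#' @param p A [phenotype_table()] with >= 2 phenotypes.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `phenotype_correlation`: list with symmetric
#'   matrices `r` and `p_value` (unit/zero diagonal), and `encodings`, the
#'   per-phenotype level maps used.
#' @export
correlate_phenotypes <- function(p, method = c("spearman", "pearson")) {
  stopifnot(inherits(p, "phenotype_table"))
  method <- match.arg(method)
  if (ncol(p) < 2) stop("need >= 2 phenotypes to correlate")
  kinds <- phenotype_kinds(p)
  encodings <- list()
  num <- matrix(NA_real_, nrow(p), ncol(p),
                dimnames = list(rownames(p), names(p)))
  for (nm in names(p)) {
    if (kinds[[nm]] == "categorical") {
      if (all(is.na(p[[nm]]))) next
      enc <- encode_categorical(p[[nm]])
      num[, nm] <- enc$values
      encodings[[nm]] <- enc$map
    } else {
      num[, nm] <- p[[nm]]
    }
  }
  k <- ncol(p)
  r <- diag(1, k); pv <- matrix(0, k, k)
  dimnames(r) <- dimnames(pv) <- list(names(p), names(p))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    x <- num[, i]; y <- num[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      pv[i, j] <- pv[j, i] <- NA_real_
    } else {
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p_value = pv, encodings = encodings, method = method),
            class = "phenotype_correlation")
}

#' @export
print.phenotype_correlation <- function(x, ...) {
  cat(sprintf("phenotype_correlation (%s) over %d phenotypes\n",
              x$method, ncol(x$r)))
  print(round(x$r, 3))
  invisible(x)
}
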