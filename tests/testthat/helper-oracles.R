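# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is written from the defining formula or by
# exhaustive enumeration, never by calling the code path it checks.

# Step-up FDR adjustment straight from the definition: sort ascending,
# adj_i = min_{j >= i} p_j * m / j, cap at 1, return in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) group
# assignments of the pooled values (no ties assumed).
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  stats <- colSums(matrix(r[combos], nrow = n1))
  # two-sided: total probability of rank sums at least as extreme,
  # measured by distance from the mean rank sum
  mu <- n1 * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# AUC by counting concordant positive-negative pairs (ties count half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Hypergeometric upper tail P(X >= k) by enumerating all C(N, n) draws of
# the query from the background.
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- draws <= K   # label elements 1..K as set members
  overlaps <- colSums(matrix(in_set, nrow = n))
  mean(overlaps >= k)
}

# Spearman rho from the rank formula (no ties): 1 - 6 sum d^2 / (n(n^2-1)).
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Write a small wide-format matrix file and return its path.
write_matrix_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny complete expression matrix with named dims.
toy_matrix <- function(values, samples, features, log2 = TRUE) {
  expression_matrix(
    matrix(values, length(samples), length(features),
           dimnames = list(samples, features)),
    log2_transformed = log2)
}

# Random valid glycoform identifiers, independent of the package's own
# generator (used for parse/format round-trip property tests).
random_glycoforms <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    gene <- paste0(sample(LETTERS, 3), collapse = "")
    gene <- if (runif(1) < 0.2) paste0(gene, "_", sample(9, 1)) else gene
    len <- sample(5:15, 1)
    pep <- paste(sample(aa, len, replace = TRUE), collapse = "")
    start <- sample(1:950, 1)
    pos <- start + sample.int(len, 1) - 1L
    k <- sample(1:3, 1)
    glycan <- paste0(sample(c("N", "H", "F", "S"), k),
                     sample(1:12, k, replace = TRUE), collapse = "")
    paste(gene, start, pep, sample(1:2, 1), pos, glycan, sep = "_")
  }, "")
}
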