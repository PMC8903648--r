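two_group_pheno <- function(n1, n2, levels = c("Tumor", "Non-Tumor")) {
  phenotype_table(
    data.frame(Pathological_Status = rep(levels, c(n1, n2)),
               row.names = sprintf("S%03d", seq_len(n1 + n2)),
               stringsAsFactors = FALSE),
    kinds = c(Pathological_Status = "categorical"))
}

test_that("Benjamini-Hochberg matches the hand-computed step-up and its bounds", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)       # m = 1: unchanged
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # monotone: preserves the order of sorted raw p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a planted strong effect is called up with fold change ~4", {
  set.seed(101)
  n <- 20
  vals <- cbind(
    planted = c(rnorm(n, 2, 0.1), rnorm(n, 0, 0.1)),
    null1 = rnorm(2 * n, 0, 0.1),
    null2 = rnorm(2 * n, 0, 0.1))
  rownames(vals) <- sprintf("S%03d", seq_len(2 * n))
  m <- expression_matrix(vals)
  de <- differential_expression(m, two_group_pheno(n, n),
                                "Pathological_Status", "Tumor", "Non-Tumor")
  row <- de[de$feature == "planted", ]
  expect_equal(row$direction, "up")
  expect_lt(row$adj_p, 0.01)
  expect_equal(row$log2_fc, 2, tolerance = 0.15 / 2)
  expect_equal(row$fold_change, 2^row$log2_fc)
  expect_equal(de$direction[de$feature != "planted"], rep("ns", 2))
})

test_that("identical groups give zero fold change and ns", {
  vals <- matrix(rep(c(1, 2, 3, 4), 2), 8, 1,
                 dimnames = list(sprintf("S%03d", 1:8), "F1"))
  m <- expression_matrix(vals)
  de <- differential_expression(m, two_group_pheno(4, 4),
                                "Pathological_Status", "Tumor", "Non-Tumor")
  expect_equal(de$log2_fc, 0)
  expect_equal(de$direction, "ns")
})

test_that("rank-sum exact mode reproduces enumeration; approximation is close", {
  # fully separated 3 vs 3: exact two-sided p = 2/20 = 0.1
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                 dimnames = list(sprintf("S%03d", 1:6), "F1"))
  m <- expression_matrix(vals)
  de <- differential_expression(m, two_group_pheno(3, 3),
                                "Pathological_Status", "Tumor", "Non-Tumor",
                                test = "wilcoxon_ranksum")
  expect_equal(de$raw_p, 0.1)
  expect_equal(de$raw_p, wilcox_enum_oracle(1:3, 4:6))

  # exact mode equals enumeration, approximation within 0.02, sizes 5..10
  set.seed(7)
  for (i in 1:12) {
    n1 <- sample(5:10, 1); n2 <- sample(5:10, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    p_exact <- suppressWarnings(
      stats::wilcox.test(x, y, exact = TRUE)$p.value)
    p_enum <- wilcox_enum_oracle(x, y)
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(p_exact, p_enum, tolerance = 1e-12)
    expect_lt(abs(p_norm - p_enum), 0.02)
  }
})

test_that("untested features (too few observations) are reported, not dropped", {
  vals <- matrix(rnorm(12), 6, 2,
                 dimnames = list(sprintf("S%03d", 1:6), c("ok", "sparse")))
  vals[1:2, "sparse"] <- NA    # leaves 1 value in group 1
  m <- expression_matrix(vals)
  de <- differential_expression(m, two_group_pheno(3, 3),
                                "Pathological_Status", "Tumor", "Non-Tumor")
  expect_equal(nrow(de), 2)
  expect_false(de$tested[de$feature == "sparse"])
  expect_true(is.na(de$adj_p[de$feature == "sparse"]))
  expect_equal(de$direction[de$feature == "sparse"], "ns")
  expect_error(
    differential_expression(m, two_group_pheno(3, 3),
                            "Pathological_Status", "Tumor", "Missing"),
    "unknown group level")
})

test_that("paired tests require complete pairings and detect a consistent shift", {
  set.seed(21)
  n <- 8
  base <- rnorm(n, 20, 1)
  vals <- matrix(c(base + 1 + rnorm(n, 0, 0.05), base), 2 * n, 1,
                 dimnames = list(sprintf("S%03d", seq_len(2 * n)), "F1"))
  p <- phenotype_table(
    data.frame(Pathological_Status = rep(c("Tumor", "Non-Tumor"), each = n),
               Patient = rep(sprintf("P%d", 1:n), 2),
               row.names = rownames(vals), stringsAsFactors = FALSE),
    kinds = c(Pathological_Status = "categorical", Patient = "categorical"))
  de <- differential_expression(expression_matrix(vals), p,
                                "Pathological_Status", "Tumor", "Non-Tumor",
                                test = "paired_t", paired_by = "Patient")
  expect_lt(de$raw_p, 1e-6)
  expect_equal(de$log2_fc, 1, tolerance = 0.1)
  # orphaned pairing key -> hard error naming it
  p_bad <- phenotype_table(
    data.frame(Pathological_Status = rep(c("Tumor", "Non-Tumor"), each = n),
               Patient = c(sprintf("P%d", 1:n), sprintf("P%d", 2:(n + 1))),
               row.names = rownames(vals), stringsAsFactors = FALSE),
    kinds = c(Pathological_Status = "categorical", Patient = "categorical"))
  expect_error(
    differential_expression(expression_matrix(vals), p_bad,
                            "Pathological_Status", "Tumor", "Non-Tumor",
                            test = "paired_t", paired_by = "Patient"),
    "P1")
  expect_error(
    differential_expression(expression_matrix(vals), p,
                            "Pathological_Status", "Tumor", "Non-Tumor",
                            test = "paired_t"),
    "paired_by")
})

test_that("type-I error is nominal on a null cohort for both tests", {
  set.seed(303)
  n <- 20; nf <- 1000
  vals <- matrix(rnorm(2 * n * nf, 20, 1), 2 * n, nf,
                 dimnames = list(sprintf("S%03d", seq_len(2 * n)),
                                 sprintf("F%d", seq_len(nf))))
  m <- expression_matrix(vals)
  ph <- two_group_pheno(n, n)
  for (tst in c("student_t", "wilcoxon_ranksum")) {
    de <- differential_expression(m, ph, "Pathological_Status",
                                  "Tumor", "Non-Tumor", test = tst)
    frac <- mean(de$raw_p < 0.05)
    expect_gte(frac, 0.03)
    expect_lte(frac, 0.07)
    expect_lte(mean(de$direction != "ns"), 0.02)
  }
})

test_that("contribution scores follow the printed equation and conserve retained variance", {
  # symmetric two-feature case: VR1 = 1, S = (0.5, 0.5)
  vals <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
                 dimnames = list(c("S1", "S2", "S3"), c("F1", "F2")))
  res <- pca_contribution(expression_matrix(vals), n_components = 1,
                          top_k = 2)
  expect_equal(res$explained_variance_ratio[1], 1)
  expect_equal(res$contribution$score, c(0.5, 0.5))

  # hand case: one retained component with loadings (0.6, -0.2) normalizes
  # to S = (0.75, 0.25); realized via a rank-1 matrix along that direction
  dirvec <- c(0.6, -0.2) / sqrt(0.4)
  X <- outer(c(-1, 0, 1), dirvec)
  dimnames(X) <- list(c("S1", "S2", "S3"), c("F1", "F2"))
  res2 <- pca_contribution(expression_matrix(X), n_components = 1, top_k = 2)
  expect_equal(res2$contribution$score, c(0.75, 0.25))
  expect_equal(res2$top_features[1], "F1")

  # conservation: sum_j S_j = sum_i VR_i over retained components, 1e-9
  set.seed(17)
  for (i in 1:10) {
    ns <- sample(5:15, 1); nf <- sample(3:40, 1)
    Xr <- matrix(rnorm(ns * nf), ns, nf,
                 dimnames = list(sprintf("S%d", 1:ns), sprintf("F%d", 1:nf)))
    k <- sample(seq_len(min(ns - 1, nf)), 1)
    r <- pca_contribution(expression_matrix(Xr), n_components = k,
                          top_k = nf)
    expect_equal(sum(r$contribution$score),
                 sum(r$explained_variance_ratio[seq_len(k)]),
                 tolerance = 1e-9)
    expect_equal(r$contribution$score[order(-r$contribution$score)][1],
                 r$contribution$score[match(r$top_features[1],
                                            r$contribution$feature)])
  }
})

test_that("PCA guards: clipping, constant matrix, missing values", {
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(sprintf("S%d", 1:3), sprintf("F%d", 1:4)))
  m <- expression_matrix(vals)
  expect_warning(res <- pca_contribution(m, n_components = 10), "clipped")
  expect_equal(res$n_components, 2)
  const <- expression_matrix(
    matrix(5, 3, 2, dimnames = list(c("S1", "S2", "S3"), c("F1", "F2"))))
  expect_error(pca_contribution(const), "constant")
  vals[1, 1] <- NA
  expect_error(pca_contribution(expression_matrix(vals)), "impute")
})

test_that("z-scoring and clustering separate opposite expression blocks", {
  expect_equal(as.numeric(zscore_features(
    toy_matrix(c(1, 2, 3), c("S1", "S2", "S3"), "F1"))), c(-1, 0, 1))

  set.seed(33)
  pattern <- rnorm(10)
  vals <- cbind(
    sapply(1:5, function(i) pattern + rnorm(10, 0, 0.05)),
    sapply(1:5, function(i) -pattern + rnorm(10, 0, 0.05)))
  dimnames(vals) <- list(sprintf("S%d", 1:10),
                         c(sprintf("A%d", 1:5), sprintf("B%d", 1:5)))
  m <- expression_matrix(vals)
  cl <- cluster_features(m, k = 2)
  a <- unique(cl$assignments[sprintf("A%d", 1:5)])
  b <- unique(cl$assignments[sprintf("B%d", 1:5)])
  expect_length(a, 1); expect_length(b, 1)
  expect_true(a != b)

  # k = feature count: every feature its own cluster
  solo <- cluster_features(m, k = 10)
  expect_equal(sort(unique(solo$assignments)), 1:10)
  expect_error(cluster_features(m, k = 11), "feature count")
  expect_error(cluster_features(m, k = 0), "\\[1")
})

test_that("clustering is invariant to feature order up to label permutation", {
  set.seed(44)
  vals <- matrix(rnorm(80), 8, 10,
                 dimnames = list(sprintf("S%d", 1:8), sprintf("F%d", 1:10)))
  m <- expression_matrix(vals)
  perm <- sample(10)
  cl1 <- cluster_features(m, k = 3)$assignments
  cl2 <- cluster_features(m[, perm], k = 3)$assignments
  cl2 <- cl2[names(cl1)]
  # same partition: co-membership matrices agree
  co <- function(a) outer(a, a, "==")
  expect_identical(co(cl1), co(cl2))
})
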