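test_that("log2 transform has the closed form and guards its preconditions", {
  m <- toy_matrix(c(8, 1, 2, NA), c("S1", "S2"), c("F1", "F2"), log2 = FALSE)
  out <- log2_transform(m)
  expect_equal(unname(unclass(out)[, "F1"]), c(3, 0))
  expect_equal(unclass(out)["S1", "F2"], 1)
  expect_true(is.na(out["S2", "F2"]))
  expect_true(is_log2(out))
  expect_error(log2_transform(out), "already log2")
  bad <- toy_matrix(c(1, -2, 3, 4), c("S1", "S2"), c("F1", "F2"), log2 = FALSE)
  expect_error(log2_transform(bad), "non-positive.*S2.*F1")
})

test_that("median normalization shifts each sample to the target, even-n median included", {
  m <- toy_matrix(c(1, 1, 2, 2, 3, 3, 4, 4), c("S1", "S2"),
                  c("F1", "F2", "F3", "F4"))
  out <- median_normalize(m, target = 0)
  # odd count via a missing cell: {1,2,3} -> {-1,0,1}
  m2 <- toy_matrix(c(1, 2, 3), "S1", c("F1", "F2", "F3"))
  expect_equal(unname(unclass(median_normalize(m2))["S1", ]), c(-1, 0, 1))
  # even count uses the mid-mean median: {1,2,3,4} -> {-1.5,-0.5,0.5,1.5}
  expect_equal(unname(unclass(out)["S1", ]), c(-1.5, -0.5, 0.5, 1.5))
  # idempotent and exact within 1e-9
  again <- median_normalize(out)
  expect_equal(unclass(again), unclass(out), tolerance = 1e-12)
  meds <- apply(out, 1, median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-9))
  # a sample already at the target is unchanged
  expect_equal(unclass(median_normalize(m2)),
               unclass(median_normalize(median_normalize(m2))))
  allna <- expression_matrix(
    matrix(c(NA_real_, NA_real_, 1, 2), 2, 2, byrow = TRUE,
           dimnames = list(c("S1", "S2"), c("F1", "F2"))))
  expect_error(median_normalize(allna), "S1")
})

test_that("noise filter keeps features at or above the observed-fraction boundary", {
  vals <- matrix(1, 6, 3, dimnames = list(sprintf("S%d", 1:6),
                                          c("keep3", "drop2", "full")))
  vals[1:4, "drop2"] <- NA   # present in 2/6
  vals[1:3, "keep3"] <- NA   # present in 3/6: boundary is inclusive
  m <- expression_matrix(vals)
  res <- filter_noise_features(m, 0.5)
  expect_setequal(colnames(res$matrix), c("keep3", "full"))
  expect_equal(res$removed, "drop2")
  expect_setequal(c(colnames(res$matrix), res$removed), colnames(m))
  # retained fractions all >= threshold
  frac <- colSums(!is.na(res$matrix)) / nrow(res$matrix)
  expect_true(all(frac >= 0.5))
  # threshold 0 removes nothing
  expect_length(filter_noise_features(m, 0)$removed, 0)
})

test_that("minimum-value imputation fills by the declared unit and never touches present values", {
  vals <- matrix(c(1, NA, 3, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("F1", "F2")))
  m <- expression_matrix(vals)
  g <- impute_missing(m, "global_min", scale = 1)
  expect_equal(unclass(g)["S1", "F2"], 1)
  f <- impute_missing(m, "feature_min", scale = 1)
  expect_equal(unclass(f)["S1", "F2"], 4)  # column-wise minimum
  s <- impute_missing(m, "sample_min", scale = 1)
  expect_equal(unclass(s)["S1", "F2"], 1)  # row-wise minimum
  half <- impute_missing(m, "global_min", scale = 0.5)
  expect_equal(unclass(half)["S1", "F2"], 0.5)
  for (out in list(g, f, s, half)) {
    expect_equal(sum(is.na(out)), 0)
    expect_equal(unclass(out)[!is.na(vals)], vals[!is.na(vals)])
  }
  # complete matrix: identity for every method
  full <- toy_matrix(1:4, c("S1", "S2"), c("F1", "F2"))
  for (meth in c("global_min", "sample_min", "feature_min", "none"))
    expect_identical(unclass(impute_missing(full, meth)), unclass(full))
  # all-missing unit errors
  vals2 <- vals; vals2[, 2] <- NA
  expect_error(impute_missing(expression_matrix(vals2), "feature_min"), "F2")
  vals3 <- vals; vals3[1, ] <- NA
  expect_error(impute_missing(expression_matrix(vals3), "sample_min"), "S1")
})

test_that("imputation properties hold on random missingness", {
  set.seed(5)
  vals <- matrix(rnorm(200, 20, 3), 10, 20,
                 dimnames = list(sprintf("S%d", 1:10), sprintf("F%d", 1:20)))
  vals[sample(200, 30)] <- NA
  m <- expression_matrix(vals)
  out <- impute_missing(m, "global_min", scale = 0.8)
  expect_equal(min(out), 0.8 * min(vals, na.rm = TRUE))
  expect_equal(sum(is.na(out)), 0)
  expect_equal(unclass(out)[!is.na(vals)], vals[!is.na(vals)])
})

test_that("replicate QC reports pairwise correlation and linear-scale CV", {
  # two identical replicates -> r = 1
  m <- toy_matrix(rep(c(1, 2, 3, 4), 2), c("QC1", "QC2"),
                  c("F1", "F2", "F3", "F4"))
  qc <- qc_replicate_report(m, c("QC1", "QC2"))
  expect_equal(qc$correlations["QC1", "QC2"], 1.0)
  expect_equal(diag(qc$correlations), c(QC1 = 1, QC2 = 1))
  # reversed ordering of two features -> r = -1 (3 features needed for r)
  vals <- matrix(c(1, 2, 3, 3, 2, 1), 2, 3, byrow = TRUE,
                 dimnames = list(c("QC1", "QC2"), c("F1", "F2", "F3")))
  anti <- qc_replicate_report(expression_matrix(vals), c("QC1", "QC2"))
  expect_equal(anti$correlations["QC1", "QC2"], -1.0)
  # CV on the linear scale: linear values {1,2,3} -> sd 1, mean 2, CV 0.5
  lin <- log2(matrix(c(1, 2, 3), 3, 1,
                     dimnames = list(c("QC1", "QC2", "QC3"), "F1")))
  cv <- qc_replicate_report(expression_matrix(lin), c("QC1", "QC2", "QC3"))
  expect_equal(cv$cv$cv, 0.5)
  expect_equal(cv$median_cv, 0.5)
  expect_error(qc_replicate_report(m, c("QC1", "nope")), "nope")
})

test_that("QC correlation grid is symmetric with unit diagonal; sparse pairs excluded from mean", {
  set.seed(9)
  vals <- matrix(rnorm(30, 20, 2), 3, 10,
                 dimnames = list(c("Q1", "Q2", "Q3"), sprintf("F%d", 1:10)))
  vals[1, 1:8] <- NA   # Q1 shares only 2 features with the others
  qc <- qc_replicate_report(expression_matrix(vals), c("Q1", "Q2", "Q3"))
  expect_identical(qc$correlations, t(qc$correlations))
  expect_true(is.na(qc$correlations["Q1", "Q2"]))
  expect_equal(qc$mean_correlation, qc$correlations["Q2", "Q3"])
})
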