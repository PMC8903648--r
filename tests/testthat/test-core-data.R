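test_that("wide-format matrix reading maps sentinels to missing and locates bad cells", {
  path <- write_matrix_file(c("Sample,F1,F2",
                              "S1,1.0,",
                              "S2,4.0,5.0",
                              "S3,na,6.0"))
  m <- read_expression_matrix(path)
  expect_s3_class(m, "expr_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_true(is.na(m["S1", "F2"]))
  expect_true(is.na(m["S3", "F1"]))   # sentinel is case-insensitive
  expect_equal(sum(is.na(m)), 2)
  expect_equal(m["S2", "F1"], 4.0)

  bad <- write_matrix_file(c("Sample,F1", "S1,1.0", "S2,oops"))
  expect_error(read_expression_matrix(bad), "oops.*S2.*F1")
})

test_that("duplicate sample or feature labels are refused by name", {
  dup_f <- write_matrix_file(c("Sample,ALB,ALB", "S1,1,2"))
  expect_error(read_expression_matrix(dup_f), "ALB")
  dup_s <- write_matrix_file(c("Sample,F1", "S1,1", "S1,2"))
  expect_error(read_expression_matrix(dup_s), "S1")
})

test_that("matrix write/read round trip is lossless and preserves missingness", {
  set.seed(11)
  vals <- matrix(rnorm(60, 20, 4), 6, 10,
                 dimnames = list(sprintf("S%d", 1:6), sprintf("F%d", 1:10)))
  vals[sample(60, 7)] <- NA
  m <- expression_matrix(vals)
  for (ext in c(".csv", ".txt")) {
    path <- tempfile(fileext = ext)
    write_expression_matrix(m, path)
    back <- read_expression_matrix(path)
    expect_identical(unclass(back), unclass(m))
  }
})

test_that("phenotype tables parse kind tags and refuse untagged or unparseable columns", {
  path <- write_matrix_file(c(
    "Sample,Pathological_Status (Categorical),Tumor_Grade (Numerical)",
    "S1,Tumor,3",
    "S2,Non-Tumor,1",
    "S3,Tumor,"))
  p <- read_phenotype_table(path)
  expect_named(p, c("Pathological_Status", "Tumor_Grade"))
  expect_equal(unname(phenotype_kinds(p)), c("categorical", "numerical"))
  expect_equal(p$Tumor_Grade, c(3, 1, NA))
  expect_equal(sort(unique(p$Pathological_Status)), c("Non-Tumor", "Tumor"))

  untagged <- write_matrix_file(c("Sample,Status", "S1,Tumor"))
  expect_error(read_phenotype_table(untagged), "Status")
  badnum <- write_matrix_file(c("Sample,Grade (Numerical)", "S1,high"))
  expect_error(read_phenotype_table(badnum), "Grade.*high")
})

test_that("phenotype table write/read round trip preserves values, kinds and missingness", {
  p <- phenotype_table(
    data.frame(Status = c("Tumor", NA, "Non-Tumor"),
               Age = c(61.5, 47, NA),
               row.names = c("S1", "S2", "S3"),
               stringsAsFactors = FALSE),
    kinds = c(Status = "categorical", Age = "numerical"))
  path <- tempfile(fileext = ".txt")
  write_phenotype_table(p, path)
  back <- read_phenotype_table(path)
  expect_identical(phenotype_kinds(back), phenotype_kinds(p))
  expect_identical(back$Status, p$Status)
  expect_identical(back$Age, p$Age)
})

test_that("glycoform identifiers parse into their six fields", {
  g <- parse_glycoform("HYOU1_869_NATLAEQAK_1_869_N2H9")
  expect_equal(g$gene, "HYOU1")
  expect_equal(g$peptide_start, 869L)
  expect_equal(g$peptide_sequence, "NATLAEQAK")
  expect_equal(g$glycosite_number, 1L)
  expect_equal(g$glycosite_position, 869L)
  expect_equal(g$glycan_composition, "N2H9")
  expect_equal(glycan_composition_counts("N2H9"), c(N = 2L, H = 9L))
})

test_that("glycoform constraint violations raise targeted parse errors", {
  # site outside the peptide span [869, 877]
  expect_error(parse_glycoform("HYOU1_869_NATLAEQAK_1_900_N2H9"),
               "900.*\\[869, 877\\]")
  expect_error(parse_glycoform("HYOU1_869_NATLAEQAK"), ">=6")
  expect_error(parse_glycoform("HYOU1_abc_NATLAEQAK_1_869_N2H9"),
               "not a positive integer")
  expect_error(parse_glycoform("HYOU1_869_NATLAEQAK_1_869_2N9"),
               "malformed glycan")
})

test_that("parse/format is the identity on valid glycoforms, incl. underscore genes", {
  g <- parse_glycoform("NKX2_1_100_NVSK_1_100_N2H3")
  expect_equal(g$gene, "NKX2_1")   # gene symbols may contain underscores
  set.seed(42)
  ids <- random_glycoforms(200)
  expect_identical(format_glycoform(parse_glycoform(ids)), ids)
  expect_true(all(is_glycoform(ids)))
})

test_that("annotation join preserves order, flags unmatched rows, renders URLs", {
  db <- annotation_db(
    data.frame(gene = c("A", "C"), desc = c("alpha", "gamma"),
               stringsAsFactors = FALSE),
    key_columns = "gene",
    url_template = "https://db.example/{gene}")
  ann <- annotate_features(c("B", "A"), db)
  expect_equal(ann$feature, c("B", "A"))    # input order preserved
  expect_equal(ann$matched, c(FALSE, TRUE))
  expect_equal(ann$desc, c("", "alpha"))
  expect_equal(ann$url, c("", "https://db.example/A"))
})

test_that("glycosite-mode annotation keys on gene + position so glycans share rows", {
  db <- annotation_db(
    data.frame(gene = "HYOU1", glycosite_position = "869",
               note = "known site", stringsAsFactors = FALSE),
    key_columns = c("gene", "glycosite_position"))
  feats <- c("HYOU1_869_NATLAEQAK_1_869_N2H9",
             "HYOU1_869_NATLAEQAK_1_869_N2H8F1")
  ann <- annotate_features(feats, db, mode = "glycosite")
  expect_equal(ann$note, rep("known site", 2))
  expect_true(all(ann$matched))
})

test_that("annotation against an empty database leaves all rows unmatched without error", {
  empty <- annotation_db(data.frame(), key_columns = "gene")
  ann <- annotate_features(c("X", "Y", "Z"), empty)
  expect_equal(nrow(ann), 3)
  expect_false(any(ann$matched))
  # row count always equals input feature count
  db <- annotation_db(data.frame(gene = c("X", "Q"), stringsAsFactors = FALSE),
                      key_columns = "gene")
  expect_equal(nrow(annotate_features(c("X", "Y", "Z", "X"), db)), 4)
  expect_error(annotation_db(data.frame(other = "A"), key_columns = "gene"),
               "missing key column")
})
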