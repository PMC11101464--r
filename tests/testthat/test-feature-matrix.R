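test_that("missingness mask tracks absent cells and round-trips through CSV", {
  m <- toy_matrix()
  expect_equal(sum(m$missing_mask), 5)
  expect_true(all(is.na(m$values) == m$missing_mask))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(m, path)
  m2 <- read_feature_matrix(path, m$descriptors)
  expect_identical(m2$values, m$values)
  expect_identical(m2$missing_mask, m$missing_mask)
  expect_identical(m2$sample_ids, m$sample_ids)
})

test_that("a 3x2 CSV with one empty cell yields exactly one masked cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,f2", "a,1,2", "b,,3", "c,0,4"), path)
  schema <- feature_descriptors(c("f1", "f2"), c("LAB", "LAB"),
                                c("continuous", "continuous"))
  m <- read_feature_matrix(path, schema)
  expect_equal(sum(m$missing_mask), 1)
  expect_true(m$missing_mask["b", "f1"])
})

test_that("schema violations are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,f1", "a,1,2"), path)
  schema <- feature_descriptors("f1", "LAB", "continuous")
  expect_error(read_feature_matrix(path, schema), "duplicated column")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,zz", "a,1,2"), path2)
  expect_error(read_feature_matrix(path2, schema), "not in schema")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1", "a,abc"), path3)
  expect_error(read_feature_matrix(path3, schema), "non-numeric.*f1")

  expect_error(feature_descriptors(c("x", "x"), "CUI", "binary"),
               "duplicate")
  expect_error(feature_descriptors("x", "CUI", "continuous"),
               "must be binary")
})

test_that("configurable missingness sentinels are honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,f2", "a,NA,2", "b,1,NaN"), path)
  schema <- feature_descriptors(c("f1", "f2"), c("LAB", "LAB"),
                                c("continuous", "continuous"))
  m <- read_feature_matrix(path, schema, na = c("", "NA", "NaN"))
  expect_equal(sum(m$missing_mask), 2)
})

test_that("completeness counts samples with any extracted value per category", {
  m <- toy_matrix()
  comp <- compute_completeness(m)
  expect_equal(unname(comp["CUI"]), 1)
  expect_equal(unname(comp["RAD"]), 2 / 3)
  expect_equal(unname(comp["LAB"]), 1 / 3)
  expect_true(all(comp >= 0 & comp <= 1))

  # all-missing and fully observed extremes
  desc <- feature_descriptors(c("u", "v"), c("CUI", "LAB"),
                              c("binary", "continuous"))
  allmiss <- feature_matrix(matrix(NA_real_, 2, 2,
                                   dimnames = list(NULL, c("u", "v"))), desc)
  expect_true(all(compute_completeness(allmiss) == 0))
  full <- feature_matrix(matrix(1, 2, 2, dimnames = list(NULL, c("u", "v"))),
                         desc)
  expect_true(all(compute_completeness(full) == 1))
})

test_that("feature schemas round-trip through JSON", {
  schema <- toy_matrix()$descriptors
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_schema(schema, path)
  expect_identical(read_feature_schema(path), schema)
})

test_that("MaxInfo filter keeps samples with enough informed categories", {
  m <- toy_matrix()
  expect_equal(maxinfo(m), c(4L, 1L, 5L))
  kept <- apply_maxinfo_filter(m, 4L)
  expect_identical(kept$sample_ids, c("a", "c"))
  # identity at 0, nesting as the cutoff rises
  expect_identical(apply_maxinfo_filter(m, 0L)$sample_ids, m$sample_ids)
  for (k in 1:4) {
    hi <- apply_maxinfo_filter(m, k)$sample_ids
    lo <- apply_maxinfo_filter(m, k - 1L)$sample_ids
    expect_true(all(hi %in% lo))
  }
  expect_error(apply_maxinfo_filter(m, 6L), "cannot exceed")
})
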