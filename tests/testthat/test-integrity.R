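test_that("applicability matrix gates on metadata availability and type", {
  md <- tiny_metadata()
  study <- tiny_study()
  study$extra <- 1:8  # present in data only
  app <- applicability_matrix(study, md, id_var = "id")
  m <- app$matrix

  expect_setequal(unique(m$status),
                  intersect(c("applicable", "no-metadata", "no-data",
                              "type-mismatch"), unique(m$status)))
  # extra column has no metadata for any check
  expect_true(all(m$status[m$variable == "extra"] == "no-metadata"))
  # sbp has limits -> limit deviations applicable; no categories declared
  expect_equal(m$status[m$variable == "sbp" & m$check == "limit_deviations"],
               "applicable")
  expect_equal(m$status[m$variable == "sbp" & m$check == "inadmissible_categorical"],
               "no-metadata")
  expect_equal(m$status[m$variable == "smoking" & m$check == "inadmissible_categorical"],
               "applicable")
  # no examiner/time keys declared -> margins and loess not applicable
  expect_equal(m$status[m$variable == "sbp" & m$check == "margins"], "no-metadata")

  # the two integrity indicator rows exist
  expect_setequal(app$results$indicator_id, c("DQI-1001", "DQI-1006"))
  r1001 <- app$results[app$results$indicator_id == "DQI-1001", ]
  expect_equal(r1001$n_flagged, 1L)  # "extra"
})

test_that("a declared float accepts observed integers; strings mismatch", {
  md <- dq_metadata(data.frame(VAR_NAMES = c("id", "a", "b"),
                               DATA_TYPE = c("integer", "float", "integer")),
                    id_var = "id")
  study <- data.frame(id = 1:3, a = c(1L, 2L, 3L), b = c("1", "x", "3"))
  app <- applicability_matrix(study, md, id_var = "id")
  r <- app$results[app$results$indicator_id == "DQI-1006", ]
  expect_equal(r$n_flagged, 1L)
  expect_equal(r$descriptor[[1]]$mismatched_variables, "b")
  expect_true(all(app$matrix$status[app$matrix$variable == "b" &
                                      app$matrix$check == "univariate_outliers"]
                  == "type-mismatch"))
})

test_that("a metadata-declared missing code does not break type probing", {
  md <- tiny_metadata()
  # 99901 is a declared code for sbp, so the column still probes integer
  verdict <- check_data_type(c("120", "99901", "abc", NA), "integer",
                             metadata = md, var = "sbp")
  expect_equal(verdict$verdicts, c("convertible", "skipped", "unconvertible",
                                   "skipped"))
  expect_equal(verdict$column, "mismatch")
  expect_equal(check_data_type(c("120", "99901"), "integer",
                               metadata = md, var = "sbp")$column, "match")
})

test_that("lossless conversion rules: 1.5 is not integer, 2001-02-30 not datetime", {
  expect_equal(check_data_type(c("1", "1.5"), "integer")$n_unconvertible, 1L)
  expect_equal(check_data_type(c("1", "1.5"), "float")$n_unconvertible, 0L)
  expect_equal(check_data_type(c("2001-02-28", "2001-02-30"),
                               "datetime")$n_unconvertible, 1L)
  expect_equal(check_data_type(c("anything", "1"), "string")$n_unconvertible, 0L)
})

test_that("duplicate records and duplicated data elements are found", {
  study <- data.frame(id = c(1, 2, 3, 2), x = c(5, 6, 7, 6), x2 = c(5, 6, 7, 6))
  r <- find_duplicates(study[, c("id", "x")], id_var = "id")
  expect_equal(r$n_flagged, 1L)  # row 4 repeats row 2
  expect_equal(r$flagged[[1]]$record_id, "2")
  # keyed comparison on id only
  r2 <- find_duplicates(study, keys = "id", id_var = "id")
  expect_equal(r2$n_flagged, 1L)
  # x and x2 are byte-identical columns under different names
  r3 <- find_duplicates(study, id_var = "id")
  expect_equal(r3$descriptor[[1]]$duplicated_elements, list(c("x", "x2")))
})

test_that("record sets are matched against a roster and across tables", {
  a <- data.frame(id = c(1, 2, 3))
  b <- data.frame(id = c(2, 3, 4))
  res <- check_record_match(list(a = a, b = b), id_var = "id",
                            roster = c(1, 2, 3, 5))
  r1002 <- res[res$indicator_id == "DQI-1002", ]
  expect_equal(r1002$n_flagged, 2L)  # 5 missing, 4 surplus
  expect_equal(r1002$descriptor[[1]]$missing_ids, "5")
  expect_equal(r1002$descriptor[[1]]$surplus_ids, "4")
  r1004 <- res[res$indicator_id == "DQI-1004", ]
  expect_equal(r1004$n_flagged, 2L)  # 1 only in a, 4 only in b
  # without a roster DQI-1002 degrades to not-applicable
  res2 <- check_record_match(a, id_var = "id")
  expect_equal(res2$grading[res2$indicator_id == "DQI-1002"], "not-applicable")
})

test_that("data elements are matched against their assigned source tables", {
  md <- dq_metadata(data.frame(VAR_NAMES = c("x", "y"),
                               DATA_TYPE = c("integer", "integer"),
                               SOURCE_TABLE = c("a", "b")))
  frames <- list(a = data.frame(x = 1, y = 1), b = data.frame(y = 1))
  r <- check_element_match(frames, md)
  expect_equal(r$n_flagged, 1L)  # y appears in both tables
  expect_equal(r$descriptor[[1]]$misplaced_variables, "y")
  md2 <- dq_metadata(data.frame(VAR_NAMES = "x", DATA_TYPE = "integer"))
  expect_equal(check_element_match(frames, md2)$grading, "not-applicable")
})

test_that("value format homogeneity is assessed with and without a pattern", {
  x <- c("1999-01-02", "2000-05-06", "7.1.2001", NA)
  r <- check_value_format(x, pattern = "^\\d{4}-\\d{2}-\\d{2}$", var = "visit")
  expect_equal(r$n_flagged, 1L)
  expect_equal(r$denominator, 3L)  # NA skipped
  r2 <- check_value_format(x, var = "visit")
  expect_equal(r2$descriptor[[1]]$n_formats, 2L)
  expect_equal(r2$grading, "issue")
  expect_equal(check_value_format(c("1-2", "3-4"), var = "v")$grading, "ok")
})
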