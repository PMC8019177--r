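make_report <- function(n = 200, seed = 17, timestamp = "2026-01-01T00:00:00") {
  sim <- dq_simulate_study(n = n, seed = seed)
  rep <- dq_report(sim$study, sim$metadata, sim$rules,
                   config = list(roster = sim$roster,
                                 segment_order = sim$segment_order,
                                 covariates = "age",
                                 timestamp = timestamp, seed = seed))
  list(sim = sim, rep = rep)
}

test_that("a report runs integrity first and covers all four dimensions", {
  x <- make_report()
  rep <- x$rep
  expect_s3_class(rep, "dq_report")
  reg <- dq_registry()
  dims <- unique(reg$dimension[match(stats::na.omit(rep$results$indicator_id),
                                     reg$id)])
  expect_setequal(dims, c("integrity", "completeness", "consistency", "accuracy"))
  # every reported indicator id is registered and implemented
  ids <- stats::na.omit(unique(rep$results$indicator_id))
  expect_true(all(ids %in% reg$id[reg$implemented]))
  # summary grid gradings are well-formed
  expect_true(all(rep$summary$grading %in% c("ok", "issue", "not-applicable")))
  expect_equal(levels(factor(rep$summary$dimension,
                             c("integrity", "completeness", "consistency",
                               "accuracy"))),
               c("integrity", "completeness", "consistency", "accuracy"))
})

test_that("integrity deficits gate downstream checks", {
  md <- dq_metadata(data.frame(
    VAR_NAMES = c("id", "x"), DATA_TYPE = c("integer", "float"),
    HARD_LIMITS = c(NA, "[0;10]")), id_var = "id")
  study <- data.frame(id = 1:20, x = c(rep("banana", 20)))
  rep <- dq_report(study, md)
  m <- rep$applicability$matrix
  expect_equal(m$status[m$variable == "x" & m$check == "limit_deviations"],
               "type-mismatch")
  # no limit-deviation result was computed for the corrupt column
  expect_false(any(rep$results$indicator_id %in% c("DQI-3001") &
                     rep$results$variable == "x", na.rm = TRUE))
})

test_that("tidy and glance summarise the report", {
  x <- make_report()
  td <- generics::tidy(x$rep)
  expect_false("descriptor" %in% names(td))
  expect_equal(nrow(td), nrow(x$rep$results))
  gl <- generics::glance(x$rep)
  expect_equal(gl$n_units, 200L)
  expect_equal(gl$n_issues, sum(x$rep$results$grading == "issue"))
  expect_equal(gl$n_flagged_cells,
               sum(purrr::map_int(x$rep$results$flagged, nrow)))
})

test_that("JSON export is schema-versioned and separates descriptors", {
  x <- make_report()
  js <- dq_export_json(x$rep)
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(doc$schema_version, "1.0")
  expect_equal(doc$meta$timestamp, "2026-01-01T00:00:00")
  expect_true(length(doc$results) > 0)
  expect_true(length(doc$descriptors) > 0)
  ind <- vapply(doc$results, `[[`, "", "indicator_id")
  expect_true(all(grepl("^DQI-\\d{4}$", ind)))
  # machine-readable results carry no descriptor payloads
  expect_false(any(vapply(doc$results, function(r) "payload" %in% names(r),
                          logical(1))))
  # flag counts survive the round trip
  one <- doc$results[[which(ind == "DQI-3001")[1]]]
  row <- x$rep$results[which(x$rep$results$indicator_id == "DQI-3001")[1], ]
  expect_equal(one$n_flagged, row$n_flagged)
  expect_equal(length(one$flagged_cells), nrow(row$flagged[[1]]))
})

test_that("rendering writes a self-contained HTML and CSV bundle", {
  x <- make_report()
  out <- tempfile()
  dq_render_report(x$rep, out)
  expect_setequal(list.files(out), c("report.html", "results.csv",
                                     "summary.csv", "applicability.csv"))
  html <- readLines(file.path(out, "report.html"))
  txt <- paste(html, collapse = "\n")
  for (h in c("Integrity", "Completeness", "Consistency", "Accuracy", "Summary")) {
    expect_true(grepl(paste0("<h2>", h, "</h2>"), txt), info = h)
  }
  expect_true(grepl("2026-01-01T00:00:00", txt))
  res <- readr::read_csv(file.path(out, "results.csv"), show_col_types = FALSE)
  expect_equal(nrow(res), nrow(x$rep$results))
  # rendering twice with the injected timestamp is byte-stable
  out2 <- tempfile()
  dq_render_report(x$rep, out2)
  expect_identical(readLines(file.path(out2, "report.html")), html)
  unlink(c(out, out2), recursive = TRUE)
})

test_that("annotation columns list every indicator that fired on a cell", {
  x <- make_report()
  ann <- annotate_flags(x$sim$study, x$rep, id_var = "id")
  expect_equal(nrow(ann), nrow(x$sim$study))
  dq_cols <- grep("_dq$", names(ann), value = TRUE)
  expect_true(length(dq_cols) > 0)
  # conservation: total annotation entries equal total flagged cells with
  # variable coordinates
  n_ann <- sum(purrr::map_int(dq_cols, function(cc) {
    sum(lengths(strsplit(ann[[cc]][nzchar(ann[[cc]])], ";", fixed = TRUE)))
  }))
  res <- x$rep$results
  flags <- dplyr::bind_rows(purrr::map(seq_len(nrow(res)), function(i) {
    fl <- res$flagged[[i]]
    if (nrow(fl) == 0) return(NULL)
    fl$indicator_id <- res$indicator_id[i]
    fl
  }))
  flags <- flags[!is.na(flags$var_name), ]
  n_expected <- nrow(dplyr::distinct(flags, record_id, var_name, indicator_id))
  expect_equal(n_ann, n_expected)
  # original values are untouched
  for (v in names(x$sim$study)) expect_identical(ann[[v]], x$sim$study[[v]])
})

test_that("annotation refuses stale coordinates", {
  x <- make_report(n = 100, seed = 19)
  shrunk <- x$sim$study[1:10, ]
  expect_error(annotate_flags(shrunk, x$rep), "absent")
})

test_that("the config hash fingerprints the configuration, not the timestamp", {
  a <- make_report(n = 100, seed = 23, timestamp = "2026-01-01T00:00:00")
  b <- make_report(n = 100, seed = 23, timestamp = "2030-12-31T23:59:59")
  expect_equal(a$rep$meta$config_hash, b$rep$meta$config_hash)
  c2 <- dq_report(a$sim$study, a$sim$metadata, a$sim$rules,
                  config = list(roster = a$sim$roster,
                                segment_order = a$sim$segment_order,
                                outlier_threshold = 2, seed = 23))
  expect_false(identical(a$rep$meta$config_hash, c2$meta$config_hash))
})
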