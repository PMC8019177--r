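# Orchestration: run all applicable checks, aggregate results, export.

#' Run a complete data quality assessment
#'
#' Runs the integrity checks first; downstream checks run only for
#' variables the applicability matrix marks applicable (deficits at the
#' integrity level would invalidate their findings). Dimensions are
#' processed in the order integrity, completeness, consistency, accuracy.
#'
#' @param study A study data frame or a named list of them (the first table
#'   drives record-level checks).
#' @param metadata A [dq_metadata()] table.
#' @param rules Optional [dq_rules()] contradiction table.
#' @param config Named list of options: `id_var` (default `"id"`),
#'   `roster`, `segment_order`, `refusal_codes`, `outlier_threshold`,
#'   `min_class_size`, `multivariate_vars`, `end_digit_vars`,
#'   `loess` (logical, default `TRUE`), `timestamp` (injected for
#'   reproducible exports), `seed`.
#' @return A `dq_report` object: list with `meta`, `applicability`,
#'   `results` (one `dq_result` tibble) and `summary` (dimension-by-variable
#'   grading grid). Has [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' sim <- dq_simulate_study(n = 150, seed = 7)
#' rep <- dq_report(sim$study, sim$metadata, sim$rules,
#'                  config = list(roster = sim$roster,
#'                                segment_order = sim$segment_order))
#' glance(rep)
#' @export
dq_report <- function(study, metadata, rules = NULL, config = list()) {
  frames <- if (is.data.frame(study)) list(study = study) else study
  if (!length(frames) || !is.data.frame(frames[[1]])) {
    stop("study must be a data frame or a named list of data frames",
         call. = FALSE)
  }
  study <- frames[[1]]
  id_var <- config$id_var %||% "id"
  if (!id_var %in% names(study)) {
    stop("identifier variable ", sQuote(id_var), " not found in study data",
         call. = FALSE)
  }
  results <- list()

  # --- integrity first ------------------------------------------------------
  app <- applicability_matrix(study, metadata, id_var = id_var)
  results$applicability <- app$results
  results$duplicates <- find_duplicates(study, id_var = id_var)
  results$records <- check_record_match(frames, id_var = id_var,
                                        roster = config$roster)
  results$elements <- check_element_match(frames, metadata)
  fmt_vars <- intersect(metadata$var_name[metadata$data_type %in% c("string", "datetime")],
                        names(study))
  results$formats <- purrr::map(fmt_vars, function(v) {
    check_value_format(study[[v]], var = v, metadata = metadata,
                       id = study[[id_var]])
  })

  applicable <- function(check) {
    m <- app$matrix
    m$variable[m$check == check & m$status == "applicable"]
  }

  # --- completeness ---------------------------------------------------------
  results$unit <- unit_missingness(study, metadata, id_var)
  has_segments <- any(!is.na(metadata$segment[metadata$role == "measurement"]))
  if (has_segments) {
    results$segment <- segment_missingness(study, metadata, id_var)
  }
  im <- item_missingness(study, metadata, id_var)
  results$item <- im$results
  results$rates <- qualified_rates(study, metadata, id_var,
                                   roster = config$roster,
                                   segment_order = config$segment_order,
                                   refusal_codes = config$refusal_codes)

  # --- consistency ----------------------------------------------------------
  results$limits <- purrr::map(applicable("limit_deviations"), function(v) {
    limit_deviations(study, metadata, v, id_var)
  })
  results$categorical <- purrr::map(applicable("inadmissible_categorical"), function(v) {
    inadmissible_categorical(study, metadata, v, id_var)
  })
  if (!is.null(rules) && nrow(rules) > 0) {
    results$contradictions <- contradictions(study, rules, metadata, id_var)
  }

  # --- accuracy -------------------------------------------------------------
  results$outliers <- purrr::map(applicable("univariate_outliers"), function(v) {
    univariate_outliers(study, v, metadata, id_var,
                        threshold = config$outlier_threshold %||% 1)
  })
  mv <- config$multivariate_vars
  if (!is.null(mv) && length(intersect(mv, applicable("univariate_outliers"))) >= 2) {
    results$multivariate <- tryCatch(
      multivariate_outliers(study, intersect(mv, applicable("univariate_outliers")),
                            metadata, id_var),
      error = function(e) NULL)
  }
  results$end_digits <- purrr::map(intersect(config$end_digit_vars %||% character(),
                                             applicable("end_digits")), function(v) {
    end_digits(study, v, metadata = metadata, id_var = id_var)
  })
  results$margins <- purrr::map(applicable("margins"), function(v) {
    mdr <- md_row(metadata, v)
    margins(study, v, mdr$key_observer,
            covariates = intersect(config$covariates %||% character(), names(study)),
            min_class_size = config$min_class_size %||% 10,
            metadata = metadata, id_var = id_var)
  })
  results$varcomp <- purrr::map(applicable("varcomp"), function(v) {
    mdr <- md_row(metadata, v)
    varcomp(study, v, mdr$key_observer,
            covariates = intersect(config$covariates %||% character(), names(study)),
            min_class_size = config$min_class_size %||% 10,
            metadata = metadata, id_var = id_var)
  })
  if (isTRUE(config$loess %||% TRUE)) {
    results$loess <- purrr::map(applicable("loess_trend"), function(v) {
      mdr <- md_row(metadata, v)
      loess_trend(study, v, mdr$key_datetime, class_var = mdr$key_observer,
                  metadata = metadata, id_var = id_var)
    })
  }

  all_results <- bind_dq_results(unlist(lapply(results, function(r) {
    if (inherits(r, "dq_result")) list(r) else r
  }), recursive = FALSE))

  reg <- dq_registry()
  summary_grid <- all_results |>
    dplyr::filter(!is.na(.data$indicator_id)) |>
    dplyr::left_join(reg[, c("id", "dimension")],
                     by = c(indicator_id = "id")) |>
    dplyr::group_by(.data$dimension, .data$variable) |>
    dplyr::summarise(grading = if (any(.data$grading == "issue")) "issue"
                     else if (any(.data$grading == "ok")) "ok"
                     else "not-applicable", .groups = "drop") |>
    dplyr::arrange(factor(.data$dimension,
                          levels = c("integrity", "completeness",
                                     "consistency", "accuracy")))

  structure(list(
    meta = list(
      timestamp = config$timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      seed = config$seed,
      config_hash = config_hash(config),
      n_units = nrow(study),
      id_var = id_var
    ),
    applicability = app,
    results = all_results,
    summary = summary_grid
  ), class = "dq_report")
}

config_hash <- function(config) {
  config$timestamp <- NULL
  if (length(config) == 0) return("default")
  ser <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                          digits = NA, null = "null")
  # rolling polynomial hash; only used as a config fingerprint
  bytes <- utf8ToInt(as.character(ser))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.dq_report <- function(x, ...) {
  cat("# Data quality report (", x$meta$n_units, " units, ",
      nrow(x$results), " results)\n", sep = "")
  issues <- dplyr::filter(x$results, .data$grading == "issue")
  cat("  issues found in", nrow(issues), "results across",
      length(unique(issues$variable)), "variables/rules\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname dq_report
#' @param x A `dq_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dq_report <- function(x, ...) {
  dplyr::select(x$results, -"descriptor")
}

#' @rdname dq_report
#' @exportS3Method generics::glance
glance.dq_report <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_units = x$meta$n_units,
    n_results = nrow(r),
    n_issues = sum(r$grading == "issue"),
    n_not_applicable = sum(r$grading == "not-applicable"),
    n_flagged_cells = sum(purrr::map_int(r$flagged, nrow))
  )
}

#' Export a report as machine-readable JSON
#'
#' Schema-versioned JSON document; descriptors are carried under a distinct
#' `descriptors` key so that downstream aggregation of the machine-readable
#' indicator metrics can ignore them. Identical inputs, config and seed give
#' byte-identical output (timestamps are injected via the report config).
#'
#' @param report A [dq_report()].
#' @param path Optional output path; with `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
dq_export_json <- function(report, path = NULL) {
  res <- report$results
  keep <- !is.na(res$indicator_id)
  flat <- purrr::map(which(keep), function(i) {
    list(indicator_id = res$indicator_id[i],
         variable = res$variable[i],
         n_flagged = res$n_flagged[i],
         denominator = res$denominator[i],
         percent = if (is.na(res$percent[i])) NULL else round(res$percent[i], 1),
         grading = res$grading[i],
         flagged_cells = res$flagged[[i]])
  })
  desc <- purrr::map(which(!purrr::map_lgl(res$descriptor, is.null)), function(i) {
    list(indicator_id = if (is.na(res$indicator_id[i])) "descriptor"
         else res$indicator_id[i],
         variable = res$variable[i],
         payload = res$descriptor[[i]])
  })
  doc <- list(schema_version = "1.0",
              meta = report$meta,
              summary = report$summary,
              results = flat,
              descriptors = desc)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", force = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Render a report to a static HTML + CSV bundle
#'
#' Writes a self-contained `report.html` with one section per dimension and
#' the summary grading grid, plus `results.csv`, `summary.csv` and
#' `applicability.csv`. Re-rendering with an injected fixed timestamp is
#' byte-stable.
#'
#' @param report A [dq_report()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
dq_render_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- dplyr::select(report$results, -"flagged", -"descriptor")
  readr::write_csv(res, file.path(out_dir, "results.csv"))
  readr::write_csv(report$summary, file.path(out_dir, "summary.csv"))
  readr::write_csv(report$applicability$matrix,
                   file.path(out_dir, "applicability.csv"))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html_table <- function(df) {
    head <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>", collapse = ""), "</tr>")
    body <- apply(df, 1, function(row) {
      paste0("<tr>", paste0("<td>", esc(ifelse(is.na(row), "", as.character(row))),
                            "</td>", collapse = ""), "</tr>")
    })
    paste0("<table>", head, paste(body, collapse = "\n"), "</table>")
  }
  reg <- dq_registry()
  res2 <- dplyr::left_join(res, reg[, c("id", "dimension", "name")],
                           by = c(indicator_id = "id"))
  sections <- purrr::map_chr(c("integrity", "completeness", "consistency", "accuracy"),
                             function(dim) {
    part <- dplyr::filter(res2, .data$dimension == dim)
    body <- if (nrow(part) == 0) "<p>No applicable checks.</p>"
            else html_table(dplyr::select(part, -"dimension"))
    title <- paste0(toupper(substring(dim, 1, 1)), substring(dim, 2))
    paste0("<section><h2>", title, "</h2>", body, "</section>")
  })
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>Data quality report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 8px}h2{margin-top:1.5em}</style>",
    "</head><body>",
    "<h1>Data quality report</h1>",
    paste0("<p>Generated: ", esc(report$meta$timestamp),
           " &middot; units: ", report$meta$n_units,
           " &middot; config: ", report$meta$config_hash, "</p>"),
    "<section><h2>Summary</h2>", html_table(report$summary), "</section>",
    sections,
    "</body></html>")
  writeLines(html, file.path(out_dir, "report.html"))
  invisible(out_dir)
}

#' Annotate study data with data quality flags
#'
#' Returns a copy of the study data with one annotation column per flagged
#' variable (`<var>_dq`) listing, per cell, the indicator IDs that fired on
#' it -- simplifying subsequent data management. Original values are left
#' untouched.
#'
#' @param study The study data frame the report was computed on.
#' @param report A [dq_report()].
#' @param id_var Identifier column.
#' @return The annotated tibble.
#' @export
annotate_flags <- function(study, report, id_var = "id") {
  ids <- record_ids(study, id_var)
  res <- report$results
  flags <- dplyr::bind_rows(purrr::map(seq_len(nrow(res)), function(i) {
    fl <- res$flagged[[i]]
    if (nrow(fl) == 0) return(NULL)
    fl$indicator_id <- res$indicator_id[i]
    fl
  }))
  out <- tibble::as_tibble(study)
  if (is.null(flags) || nrow(flags) == 0) return(out)
  flags <- dplyr::filter(flags, !is.na(.data$var_name))
  stale <- !(flags$record_id %in% ids) |
    !(flags$var_name %in% names(study))
  if (any(stale)) {
    stop("flagged cells reference coordinates absent from the study data",
         call. = FALSE)
  }
  for (v in unique(flags$var_name)) {
    fv <- flags[flags$var_name == v, ]
    ann <- vapply(ids, function(rid) {
      hit <- fv$indicator_id[fv$record_id == rid]
      if (length(hit) == 0) "" else paste(sort(unique(hit)), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    out[[paste0(v, "_dq")]] <- ann
  }
  out
}
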