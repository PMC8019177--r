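# Integrity checks: compliance of study data with structural and technical
# requirements. These run first in every assessment and never fail on bad
# data -- deficits found here gate which downstream checks are applicable.

# downstream checks and the metadata each one needs
.check_requirements <- list(
  item_missingness         = list(needs = character(), types = NULL),
  limit_deviations         = list(needs = "limits", types = c("integer", "float", "datetime")),
  inadmissible_categorical = list(needs = "categories", types = c("integer", "float", "string")),
  contradictions           = list(needs = character(), types = NULL),
  univariate_outliers      = list(needs = character(), types = c("integer", "float")),
  distribution             = list(needs = character(), types = NULL),
  shape_or_scale           = list(needs = character(), types = c("integer", "float")),
  end_digits               = list(needs = character(), types = c("integer", "float")),
  margins                  = list(needs = "key_observer", types = c("integer", "float")),
  varcomp                  = list(needs = "key_observer", types = c("integer", "float")),
  loess_trend              = list(needs = "key_datetime", types = c("integer", "float"))
)

#' Applicability of checks given study data and metadata
#'
#' The entry-point diagnostic of every assessment: each variable is
#' cross-checked against the metadata (presence, declared vs. observed data
#' type, availability of the metadata fields each downstream check needs).
#' Two indicators are computed alongside: unexpected data elements
#' (variables present in exactly one of study data and metadata, DQI-1001)
#' and data type mismatches (DQI-1006). The resulting matrix gates which
#' checks [dq_report()] will run; it never raises on malformed data.
#'
#' @param study A study data frame (one row per observational unit).
#' @param metadata A [dq_metadata()] table.
#' @param id_var Name of the record identifier column.
#' @return A `dq_applicability` object: list with
#'   \describe{
#'     \item{matrix}{long tibble `(variable, check, status)` with status one
#'       of `applicable`, `no-metadata`, `no-data`, `type-mismatch`;}
#'     \item{results}{a [dq_result_row()] tibble for DQI-1001 and DQI-1006.}
#'   }
#' @examples
#' md <- dq_metadata(data.frame(VAR_NAMES = c("id", "sbp"),
#'                              DATA_TYPE = c("integer", "float"),
#'                              HARD_LIMITS = c(NA, "[60;300]")), id_var = "id")
#' applicability_matrix(data.frame(id = 1:3, sbp = c(120, 135, 110)), md)
#' @export
applicability_matrix <- function(study, metadata, id_var = "id") {
  md_vars <- metadata$var_name
  st_vars <- names(study)
  one_sided <- c(setdiff(md_vars, st_vars), setdiff(st_vars, md_vars))
  both <- intersect(md_vars, st_vars)

  observed <- purrr::map_chr(both, function(v) {
    probe_type(study[[v]], md_row(metadata, v)) %||% NA_character_
  })
  declared <- metadata$data_type[match(both, metadata$var_name)]
  # observed integers satisfy a declared float; an all-missing column cannot
  # contradict the declaration
  type_ok <- is.na(observed) | observed == declared |
    (observed == "integer" & declared == "float")
  mismatched <- both[!type_ok]

  checks <- names(.check_requirements)
  all_vars <- union(md_vars, st_vars)
  grid <- tidyr::expand_grid(variable = all_vars, check = checks)
  grid$status <- purrr::pmap_chr(grid, function(variable, check) {
    if (!(variable %in% st_vars)) return("no-data")
    if (!(variable %in% md_vars)) return("no-metadata")
    mdr <- md_row(metadata, variable)
    req <- .check_requirements[[check]]
    if (variable %in% mismatched && !is.null(req$types)) return("type-mismatch")
    if (!is.null(req$types) && !mdr$data_type %in% req$types) return("no-metadata")
    has <- vapply(req$needs, function(need) {
      switch(need,
        limits = !is.null(mdr$hard_limits) || !is.null(mdr$soft_limits) ||
          !is.null(mdr$detection_limits),
        categories = length(mdr$categories) > 0,
        key_observer = !is.na(mdr$key_observer) && mdr$key_observer %in% st_vars,
        key_datetime = !is.na(mdr$key_datetime) && mdr$key_datetime %in% st_vars
      )
    }, logical(1))
    if (all(has)) "applicable" else "no-metadata"
  })

  results <- bind_dq_results(
    dq_result_row("DQI-1001", "study-level",
                  n_flagged = length(one_sided),
                  denominator = length(all_vars),
                  descriptor = list(unmatched_variables = one_sided)),
    dq_result_row("DQI-1006", "study-level",
                  n_flagged = length(mismatched),
                  denominator = length(both),
                  descriptor = list(mismatched_variables = mismatched,
                                    observed_types = stats::setNames(observed, both)))
  )
  structure(list(matrix = grid, results = results),
            class = "dq_applicability")
}

#' @export
print.dq_applicability <- function(x, ...) {
  cat("# Applicability matrix (", length(unique(x$matrix$variable)),
      " variables x ", length(unique(x$matrix$check)), " checks)\n", sep = "")
  print(x$results)
  invisible(x)
}

#' Duplicate records and duplicated data elements
#'
#' Counts records beyond the first occurrence in each duplicate group
#' (DQI-1003). With `keys` given, records are compared on those columns
#' only; otherwise full records are compared. Byte-identical columns under
#' different names are additionally reported as duplicated data elements.
#'
#' @param study Study data frame.
#' @param keys Character vector of key columns; `NULL` compares full records.
#' @param id_var Identifier column used for flagged-cell coordinates.
#' @return A `dq_result` tibble (DQI-1003); its descriptor holds the
#'   duplicated-element pairs.
#' @export
find_duplicates <- function(study, keys = NULL, id_var = NULL) {
  cmp <- if (is.null(keys) || length(keys) == 0) study else study[, keys, drop = FALSE]
  dup <- duplicated(cmp)
  ids <- if (!is.null(id_var) && id_var %in% names(study)) {
    record_ids(study, id_var)
  } else {
    as.character(seq_len(nrow(study)))
  }
  # duplicated data elements: identical column content under different names
  pairs <- list()
  cols <- names(study)
  if (length(cols) > 1) {
    keyed <- vapply(study, function(col) paste(as.character(col), collapse = "\r"),
                    character(1))
    for (i in seq_along(cols)[-1]) {
      hit <- which(keyed[seq_len(i - 1)] == keyed[i])
      if (length(hit)) pairs[[length(pairs) + 1]] <- c(cols[hit[1]], cols[i])
    }
  }
  dq_result_row("DQI-1003", "study-level",
                n_flagged = sum(dup),
                denominator = nrow(study),
                flagged = cells(ids[dup], NA_character_),
                descriptor = list(duplicated_elements = pairs))
}

#' Correspondence of record sets across tables and against a roster
#'
#' DQI-1002 compares the observed record identifiers with an expected
#' roster (symmetric difference); without a roster the check degrades to
#' duplicate-identifier detection and is graded not-applicable. DQI-1004
#' compares identifiers pairwise across study tables (symmetric difference
#' in both directions).
#'
#' @param frames Named list of study data frames.
#' @param id_var Identifier column, present in every frame.
#' @param roster Optional vector of expected record identifiers.
#' @return A `dq_result` tibble with one DQI-1002 row and one DQI-1004 row
#'   per frame pair.
#' @export
check_record_match <- function(frames, id_var = "id", roster = NULL) {
  if (is.data.frame(frames)) frames <- list(study = frames)
  ids <- purrr::map(frames, record_ids, id_var = id_var)

  res <- list()
  if (!is.null(roster)) {
    roster <- as.character(roster)
    all_ids <- unique(unlist(ids))
    missing_ids <- setdiff(roster, all_ids)
    surplus_ids <- setdiff(all_ids, roster)
    res[[length(res) + 1]] <- dq_result_row(
      "DQI-1002", "study-level",
      n_flagged = length(missing_ids) + length(surplus_ids),
      denominator = length(roster),
      descriptor = list(missing_ids = missing_ids, surplus_ids = surplus_ids))
  } else {
    dup_n <- sum(vapply(ids, function(v) sum(duplicated(v)), integer(1)))
    res[[length(res) + 1]] <- dq_result_row(
      "DQI-1002", "study-level", n_flagged = dup_n,
      denominator = sum(lengths(ids)),
      grading = "not-applicable",
      descriptor = list(note = "no roster supplied; duplicate identifiers only"))
  }
  nm <- names(frames)
  if (length(frames) >= 2) {
    for (i in seq_along(frames)[-length(frames)]) {
      for (j in seq((i + 1), length(frames))) {
        mism <- union(setdiff(ids[[i]], ids[[j]]), setdiff(ids[[j]], ids[[i]]))
        res[[length(res) + 1]] <- dq_result_row(
          "DQI-1004", paste(nm[i], nm[j], sep = " ~ "),
          n_flagged = length(mism),
          denominator = length(union(ids[[i]], ids[[j]])),
          descriptor = list(mismatching_ids = mism))
      }
    }
  }
  bind_dq_results(res)
}

#' Correspondence of data elements with their expected source tables
#'
#' Flags variables that appear in a table other than the one the metadata
#' assigns them to, or in several tables at once (DQI-1005). Requires the
#' optional `SOURCE_TABLE` metadata column; without it the check is graded
#' not-applicable.
#'
#' @param frames Named list of study data frames.
#' @param metadata A [dq_metadata()] table.
#' @return A `dq_result` tibble (DQI-1005).
#' @export
check_element_match <- function(frames, metadata) {
  if (is.data.frame(frames)) frames <- list(study = frames)
  assigned <- metadata$source_table
  if (all(is.na(assigned))) {
    return(dq_result_row("DQI-1005", "study-level", 0L,
                         denominator = nrow(metadata),
                         grading = "not-applicable",
                         descriptor = list(note = "metadata has no SOURCE_TABLE assignments")))
  }
  misplaced <- character()
  for (i in seq_len(nrow(metadata))) {
    v <- metadata$var_name[i]
    expect_tab <- assigned[i]
    if (is.na(expect_tab)) next
    found_in <- names(frames)[vapply(frames, function(f) v %in% names(f), logical(1))]
    if (!(length(found_in) == 1 && found_in == expect_tab)) misplaced <- c(misplaced, v)
  }
  dq_result_row("DQI-1005", "study-level",
                n_flagged = length(misplaced),
                denominator = sum(!is.na(assigned)),
                descriptor = list(misplaced_variables = misplaced))
}

#' Homogeneity of value formats within a column
#'
#' With a pattern supplied, counts observed cells not matching it
#' (DQI-1007, cell level). Without one, the distinct textual formats of the
#' column are inferred (digits collapsed to `d`, letters to `a`) and their
#' number reported: more than one distinct format means the column is
#' inhomogeneous (column level). Both readings are returned because the
#' indicator is meaningful at either granularity.
#'
#' @param x Vector of raw cell values.
#' @param pattern Optional regular expression every value must match.
#' @param var Variable name for the result row.
#' @param metadata,id Optional metadata (code-aware skipping) and record ids.
#' @return A `dq_result` tibble (DQI-1007); descriptor holds the inferred
#'   format table.
#' @export
check_value_format <- function(x, pattern = NULL, var = "value",
                               metadata = NULL, id = NULL) {
  mdr <- if (!is.null(metadata)) md_row(metadata, var) else NULL
  cls <- classify_cells(x, mdr)
  obs <- as.character(x)[cls == "observed"]
  ids <- if (is.null(id)) as.character(seq_along(x)) else as.character(id)
  ids <- ids[cls == "observed"]
  if (!is.null(pattern)) {
    ok <- tryCatch(grepl(pattern, obs),
                   error = function(e) stop("invalid format pattern: ",
                                            conditionMessage(e), call. = FALSE))
    fmt_tab <- table(infer_format(obs))
    return(dq_result_row("DQI-1007", var,
                         n_flagged = sum(!ok), denominator = length(obs),
                         flagged = cells(ids[!ok], var),
                         descriptor = list(formats = as.list(fmt_tab))))
  }
  fmts <- infer_format(obs)
  fmt_tab <- table(fmts)
  n_formats <- length(fmt_tab)
  dq_result_row("DQI-1007", var,
                n_flagged = if (n_formats > 1) length(obs) - max(fmt_tab) else 0L,
                denominator = length(obs),
                grading = if (n_formats > 1) "issue" else "ok",
                descriptor = list(n_formats = n_formats, formats = as.list(fmt_tab)))
}

# "2001-01-01" -> "dddd-dd-dd"; "1.5" -> "d.d"; "abc" -> "a"
infer_format <- function(x) {
  out <- gsub("\\d+", "d", x)
  gsub("[A-Za-z]+", "a", out)
}
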