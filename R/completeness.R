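# Completeness: missing data at unit, segment and item level, crude and
# qualified. Missingness staging follows data collection: unit nonentry (1),
# longitudinal drop-out (2), segment nonparticipation (3), item missingness
# (4). Item-level denominators exclude units already counted at stages 1/3.

unit_missing_ids <- function(study, metadata, id_var) {
  vars <- vars_with_role(metadata, study, "measurement")
  if (length(vars) == 0) return(character())
  ids <- record_ids(study, id_var)
  miss <- vapply(vars, function(v) {
    is_missing_any(study[[v]], md_row(metadata, v))
  }, logical(nrow(study)))
  if (nrow(study) == 1) miss <- matrix(miss, nrow = 1)
  ids[rowSums(!miss) == 0]
}

#' Unit missingness
#'
#' Flags observational units for which every measurement variable is missing
#' (system-missing or qualified-coded). Identifier and process variables do
#' not count: a record carrying only an examiner ID is still all-missing.
#'
#' @param study Study data frame.
#' @param metadata A [dq_metadata()] table.
#' @param id_var Identifier column.
#' @return A `dq_result` tibble (one study-level row).
#' @export
unit_missingness <- function(study, metadata, id_var = "id") {
  vars <- vars_with_role(metadata, study, "measurement")
  if (length(vars) == 0) {
    return(dq_result_row("DQI-2001", "study-level", 0L, 0L,
                         grading = "not-applicable",
                         descriptor = list(note = "no measurement variables"),
                         subclass = "dq_unit_missingness"))
  }
  flagged_ids <- unit_missing_ids(study, metadata, id_var)
  dq_result_row("DQI-2001", "study-level",
                n_flagged = length(flagged_ids), denominator = nrow(study),
                flagged = cells(flagged_ids, NA_character_),
                descriptor = list(level = "unit"),
                subclass = "dq_unit_missingness")
}

segment_vars <- function(metadata, study) {
  segs <- metadata[metadata$role == "measurement" & !is.na(metadata$segment) &
                     metadata$var_name %in% names(study), ]
  split(segs$var_name, segs$segment)
}

segment_missing_ids <- function(study, metadata, id_var, exclude = character()) {
  ids <- record_ids(study, id_var)
  keep <- !(ids %in% exclude)
  purrr::map(segment_vars(metadata, study), function(vars) {
    miss <- vapply(vars, function(v) is_missing_any(study[[v]], md_row(metadata, v)),
                   logical(nrow(study)))
    if (nrow(study) == 1) miss <- matrix(miss, nrow = 1)
    ids[keep & rowSums(!miss) == 0]
  })
}

#' Segment missingness
#'
#' Per study segment (an examination block such as blood pressure
#' measurement), counts units with all of the segment's measurement
#' variables missing. Units already flagged as unit-missing are excluded
#' (stage 1 precedes stage 3), so the denominator is the number of units
#' that entered the study. The descriptor carries the unit-by-segment
#' participation pattern.
#'
#' @inheritParams unit_missingness
#' @return A `dq_result` tibble with one row per segment.
#' @export
segment_missingness <- function(study, metadata, id_var = "id") {
  segs <- segment_vars(metadata, study)
  if (length(segs) == 0) {
    stop("no segments with measurement variables in metadata", call. = FALSE)
  }
  if (any(lengths(segs) == 0)) {
    stop("segment without variables: ",
         paste(names(segs)[lengths(segs) == 0], collapse = ", "), call. = FALSE)
  }
  unit_ids <- unit_missing_ids(study, metadata, id_var)
  seg_ids <- segment_missing_ids(study, metadata, id_var, exclude = unit_ids)
  denom <- nrow(study) - length(unit_ids)

  ids <- record_ids(study, id_var)
  pattern <- tibble::tibble(record_id = ids[!(ids %in% unit_ids)])
  for (s in names(seg_ids)) pattern[[s]] <- !(pattern$record_id %in% seg_ids[[s]])

  rows <- purrr::imap(seg_ids, function(fl, seg) {
    dq_result_row("DQI-2001", seg,
                  n_flagged = length(fl), denominator = denom,
                  flagged = cells(fl, NA_character_),
                  descriptor = list(level = "segment",
                                    participation_pattern = pattern),
                  subclass = "dq_segment_missingness")
  })
  as_dq_result(bind_dq_results(rows), "dq_segment_missingness")
}

#' Item missingness with qualified breakdown
#'
#' For every measurement variable, tabulates observed values, data fields
#' without any entry (system missing), and qualified missing and jump codes.
#' The per-variable denominator is staged: units flagged at the unit level
#' and, for the variable's segment, at the segment level are excluded. The
#' breakdown obeys the conservation identity
#' `n_observed + n_system_missing + sum(per_code) + sum(per_jump) = n_expected`.
#'
#' Three indicators result: crude missing fields (DQI-2001), missing due to
#' specified reason (DQI-2005), and uncertain missingness status
#' (DQI-1008: system-missing cells in variables that declare missing codes,
#' where a qualified code was expected).
#'
#' @inheritParams unit_missingness
#' @param staged Exclude unit-/segment-missing units from denominators
#'   (default `TRUE`).
#' @return A `dq_item_missingness` object: list with `breakdown` (one tibble
#'   row per variable, `per_code`/`per_jump` as named list columns) and
#'   `results` (a `dq_result` tibble).
#' @export
item_missingness <- function(study, metadata, id_var = "id", staged = TRUE) {
  vars <- vars_with_role(metadata, study, "measurement")
  ids <- record_ids(study, id_var)
  unit_ids <- if (staged) unit_missing_ids(study, metadata, id_var) else character()
  seg_ids <- if (staged) segment_missing_ids(study, metadata, id_var, exclude = unit_ids)
             else list()

  per_var <- purrr::map(vars, function(v) {
    mdr <- md_row(metadata, v)
    excl <- unit_ids
    if (!is.na(mdr$segment) && mdr$segment %in% names(seg_ids)) {
      excl <- c(excl, seg_ids[[mdr$segment]])
    }
    keep <- !(ids %in% excl)
    x <- study[[v]][keep]
    kid <- ids[keep]
    cls <- classify_cells(x, mdr)
    code_chr <- normalize_code(as.character(x))
    per_code <- purrr::map_int(names(mdr$missing_codes) %||% character(),
                               ~ sum(cls == "missing_code" & code_chr == .x, na.rm = TRUE))
    names(per_code) <- names(mdr$missing_codes)
    per_jump <- purrr::map_int(names(mdr$jump_codes) %||% character(),
                               ~ sum(cls == "jump_code" & code_chr == .x, na.rm = TRUE))
    names(per_jump) <- names(mdr$jump_codes)
    list(
      breakdown = tibble::tibble(
        variable = v,
        n_expected = length(x),
        n_observed = sum(cls == "observed"),
        n_system_missing = sum(cls == "system"),
        per_code = list(as.list(per_code)),
        per_jump = list(as.list(per_jump))
      ),
      system_ids = kid[cls == "system"],
      missing_ids = kid[cls != "observed"],
      has_codes = length(mdr$missing_codes) > 0
    )
  })

  breakdown <- dplyr::bind_rows(purrr::map(per_var, "breakdown"))
  results <- purrr::map2(per_var, vars, function(pv, v) {
    b <- pv$breakdown
    n_missing <- b$n_expected - b$n_observed
    n_coded <- n_missing - b$n_system_missing
    out <- list(
      dq_result_row("DQI-2001", v, n_flagged = n_missing,
                    denominator = b$n_expected,
                    flagged = cells(pv$missing_ids, v),
                    descriptor = list(level = "item"),
                    subclass = "dq_item_missingness_result"),
      dq_result_row("DQI-2005", v, n_flagged = n_coded,
                    denominator = b$n_expected,
                    descriptor = list(per_code = b$per_code[[1]],
                                      per_jump = b$per_jump[[1]]))
    )
    if (pv$has_codes) {
      out[[3]] <- dq_result_row("DQI-1008", v,
                                n_flagged = b$n_system_missing,
                                denominator = b$n_expected,
                                flagged = cells(pv$system_ids, v))
    }
    bind_dq_results(out)
  })
  structure(list(breakdown = breakdown, results = bind_dq_results(results)),
            class = "dq_item_missingness")
}

#' @export
print.dq_item_missingness <- function(x, ...) {
  cat("# Item missingness across", nrow(x$breakdown), "variables\n")
  print(x$breakdown)
  invisible(x)
}

#' Qualified response rates: nonresponse, refusal, drop-out
#'
#' \describe{
#'   \item{DQI-2002 (non-response)}{eligible units on the roster for which no
#'     information could be obtained: absent from the study data or without
#'     any observed value *and* without any qualified code. A unit of
#'     all-refusals did respond (with refusals), so it is not nonresponse.}
#'   \item{DQI-2003 (refusal)}{roster units that are present but have no
#'     observed measurement and at least one refusal-coded cell.}
#'   \item{DQI-2004 (drop-out)}{participants who completed at least one
#'     segment and then prematurely abandoned the study: all segments after
#'     the last completed one (in `segment_order`) are entirely missing.
#'     Intermittent segment missingness is not drop-out.}
#' }
#'
#' @inheritParams unit_missingness
#' @param roster Vector of eligible record identifiers (needed for
#'   DQI-2002/2003; without it both are graded not-applicable).
#' @param segment_order Character vector giving the chronological order of
#'   segments (needed for DQI-2004).
#' @param refusal_codes Codes counting as refusal; default: every missing
#'   code whose label contains "refus".
#' @return A `dq_result` tibble with up to three rows.
#' @export
qualified_rates <- function(study, metadata, id_var = "id", roster = NULL,
                            segment_order = NULL, refusal_codes = NULL) {
  vars <- vars_with_role(metadata, study, "measurement")
  ids <- record_ids(study, id_var)
  res <- list()

  cls_mat <- vapply(vars, function(v) classify_cells(study[[v]], md_row(metadata, v)),
                    character(nrow(study)))
  if (nrow(study) == 1) cls_mat <- matrix(cls_mat, nrow = 1, dimnames = list(NULL, vars))
  any_observed <- rowSums(cls_mat == "observed") > 0
  any_coded <- rowSums(cls_mat == "missing_code" | cls_mat == "jump_code") > 0

  if (is.null(refusal_codes)) {
    refusal_codes <- unique(unlist(purrr::map(metadata$missing_codes, function(mc) {
      names(mc)[grepl("refus", mc, ignore.case = TRUE)]
    })))
  }

  if (!is.null(roster)) {
    roster <- as.character(roster)
    responded <- ids[any_observed | any_coded]
    nonresp <- setdiff(roster, responded)
    res[[length(res) + 1]] <- dq_result_row(
      "DQI-2002", "study-level", n_flagged = length(nonresp),
      denominator = length(roster),
      flagged = cells(nonresp, NA_character_))

    has_refusal <- rep(FALSE, nrow(study))
    for (v in vars) {
      code_chr <- normalize_code(as.character(study[[v]]))
      has_refusal <- has_refusal | (cls_mat[, v] == "missing_code" &
                                      code_chr %in% refusal_codes)
    }
    refusers <- ids[!any_observed & has_refusal & ids %in% roster]
    res[[length(res) + 1]] <- dq_result_row(
      "DQI-2003", "study-level", n_flagged = length(refusers),
      denominator = length(roster),
      flagged = cells(refusers, NA_character_))
  } else {
    res[[length(res) + 1]] <- dq_result_row("DQI-2002", "study-level", 0L, 0L,
                                            grading = "not-applicable")
    res[[length(res) + 1]] <- dq_result_row("DQI-2003", "study-level", 0L, 0L,
                                            grading = "not-applicable")
  }

  if (!is.null(segment_order)) {
    segs <- segment_vars(metadata, study)
    segment_order <- intersect(segment_order, names(segs))
    if (length(segment_order) < 2) {
      stop("segment_order must name at least two known segments", call. = FALSE)
    }
    completed <- vapply(segment_order, function(s) {
      miss <- vapply(segs[[s]], function(v) is_missing_any(study[[v]], md_row(metadata, v)),
                     logical(nrow(study)))
      if (nrow(study) == 1) miss <- matrix(miss, nrow = 1)
      rowSums(!miss) > 0
    }, logical(nrow(study)))
    if (nrow(study) == 1) completed <- matrix(completed, nrow = 1)
    n_done <- rowSums(completed)
    last_done <- apply(completed, 1, function(z) if (any(z)) max(which(z)) else 0L)
    dropout <- n_done > 0 & last_done < length(segment_order)
    participants <- n_done > 0
    res[[length(res) + 1]] <- dq_result_row(
      "DQI-2004", "study-level", n_flagged = sum(dropout),
      denominator = sum(participants),
      flagged = cells(ids[dropout], NA_character_))
  }
  bind_dq_results(res)
}
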