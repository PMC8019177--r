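# Consistency: Boolean-type checks for inadmissible/uncertain values and
# contradictory value combinations.

#' Limit deviations for numeric and date-time variables
#'
#' Checks observed values against the limit intervals declared in the
#' metadata. Hard-limit violations are inadmissible values (DQI-3001 for
#' numeric, DQI-3002 for date-time variables); values inside the hard limits
#' but outside the soft limits are improbable/uncertain (DQI-3006/3007).
#' Counts above and below each threshold are reported separately in the
#' descriptor, together with histogram data for plotting. Values outside the
#' detection limits are a device-censoring count, reported in the descriptor
#' but not graded as inadmissibility. Qualified missing/jump codes are
#' stripped before any comparison: a missing code is never a limit
#' violation.
#'
#' @param study Study data frame.
#' @param metadata A [dq_metadata()] table.
#' @param var Variable to check.
#' @param id_var Identifier column.
#' @return A `dq_result` tibble (hard and soft rows as applicable).
#' @export
limit_deviations <- function(study, metadata, var, id_var = "id") {
  mdr <- md_row(metadata, var)
  if (is.null(mdr)) stop("no metadata for variable ", sQuote(var), call. = FALSE)
  if (is.null(mdr$hard_limits) && is.null(mdr$soft_limits) &&
      is.null(mdr$detection_limits)) {
    return(dq_result_row("DQI-3001", var, 0L, 0L, grading = "not-applicable",
                         descriptor = list(note = "no limits declared")))
  }
  is_dt <- mdr$data_type == "datetime"
  ids <- record_ids(study, id_var)
  cls <- classify_cells(study[[var]], mdr)
  idx <- which(cls == "observed")
  vals <- if (is_dt) as.numeric(parse_iso_datetime(as.character(study[[var]])[idx]))
          else suppressWarnings(as.numeric(as.character(study[[var]])[idx]))
  keep <- !is.na(vals)
  vals <- vals[keep]; idx <- idx[keep]
  n <- length(vals)

  hard_id <- if (is_dt) "DQI-3002" else "DQI-3001"
  soft_id <- if (is_dt) "DQI-3007" else "DQI-3006"
  rows <- list()

  below_above <- function(interval) {
    below <- if (interval$lower_closed) vals < interval$lower else vals <= interval$lower
    above <- if (interval$upper_closed) vals > interval$upper else vals >= interval$upper
    list(below = below, above = above, out = below | above)
  }
  hist_payload <- local({
    h <- if (n > 1 && length(unique(vals)) > 1) graphics::hist(vals, plot = FALSE) else NULL
    list(breaks = h$breaks, counts = h$counts,
         hard = if (!is.null(mdr$hard_limits)) c(mdr$hard_limits$lower, mdr$hard_limits$upper),
         soft = if (!is.null(mdr$soft_limits)) c(mdr$soft_limits$lower, mdr$soft_limits$upper))
  })

  hard_out <- rep(FALSE, n)
  if (!is.null(mdr$hard_limits)) {
    ba <- below_above(mdr$hard_limits)
    hard_out <- ba$out
    rows[[length(rows) + 1]] <- dq_result_row(
      hard_id, var, n_flagged = sum(ba$out), denominator = n,
      flagged = cells(ids[idx[ba$out]], var),
      descriptor = c(list(n_below = sum(ba$below), n_above = sum(ba$above),
                          limits = format(mdr$hard_limits)), hist_payload),
      subclass = "dq_limit_deviations")
  }
  if (!is.null(mdr$soft_limits)) {
    ba <- below_above(mdr$soft_limits)
    uncertain <- ba$out & !hard_out
    rows[[length(rows) + 1]] <- dq_result_row(
      soft_id, var, n_flagged = sum(uncertain), denominator = n,
      flagged = cells(ids[idx[uncertain]], var),
      descriptor = c(list(n_below = sum(ba$below & !hard_out),
                          n_above = sum(ba$above & !hard_out),
                          limits = format(mdr$soft_limits)), hist_payload),
      subclass = "dq_limit_deviations")
  }
  if (!is.null(mdr$detection_limits)) {
    ba <- below_above(mdr$detection_limits)
    rows[[length(rows) + 1]] <- dq_result_row(
      hard_id, var, n_flagged = 0L, denominator = n,
      grading = "ok",
      descriptor = list(censoring = list(n_below = sum(ba$below),
                                         n_above = sum(ba$above),
                                         limits = format(mdr$detection_limits))),
      subclass = "dq_limit_deviations")
  }
  as_dq_result(bind_dq_results(rows), "dq_limit_deviations")
}

#' Inadmissible categorical values
#'
#' Flags observed cells whose value is neither an admissible category nor a
#' declared missing/jump code (DQI-3003). The descriptor tabulates observed
#' vs. expected levels, including any surplus levels found.
#'
#' @inheritParams limit_deviations
#' @return A `dq_result` tibble (one row).
#' @export
inadmissible_categorical <- function(study, metadata, var, id_var = "id") {
  mdr <- md_row(metadata, var)
  if (is.null(mdr) || length(mdr$categories) == 0) {
    return(dq_result_row("DQI-3003", var, 0L, 0L, grading = "not-applicable",
                         descriptor = list(note = "no admissible categories declared")))
  }
  ids <- record_ids(study, id_var)
  cls <- classify_cells(study[[var]], mdr)
  idx <- which(cls == "observed")
  vals <- normalize_code(as.character(study[[var]])[idx])
  bad <- !(vals %in% names(mdr$categories))
  observed_tab <- table(vals)
  dq_result_row("DQI-3003", var,
                n_flagged = sum(bad), denominator = length(vals),
                flagged = cells(ids[idx[bad]], var),
                descriptor = list(
                  expected_levels = names(mdr$categories),
                  observed_levels = as.list(observed_tab),
                  surplus_levels = setdiff(names(observed_tab), names(mdr$categories))),
                subclass = "dq_inadmissible_categorical")
}

# --- contradiction rules ----------------------------------------------------

.side_types <- c("set", "range", "trange", "miss")

#' The contradiction predicate catalog
#'
#' A contradiction rule compares two data values of the same observational
#' unit; a unit is flagged when both side conditions hold. Each side is one
#' of four condition templates:
#' \describe{
#'   \item{set}{the value is in a category set (`params`: codes separated by
#'     `|`, e.g. `"1|2"`);}
#'   \item{range}{the value lies in a numeric interval (`params`: interval
#'     literal, e.g. `"[60;100)"`);}
#'   \item{trange}{the value lies in a date-time interval;}
#'   \item{miss}{the value is qualified missing or jump-coded (`params`
#'     optionally restricts to specific codes).}
#' }
#' giving a 4 x 4 = 16 member catalog of two-variable comparison templates.
#' Codes are `"<sideA>_<sideB>"`, e.g. `"set_set"` or `"range_miss"`. Units
#' where either side is qualified-missing never fire a value-comparison
#' (set/range/trange) condition.
#'
#' @return Character vector of the 16 predicate codes.
#' @examples
#' dq_predicates()
#' @export
dq_predicates <- function() {
  as.vector(outer(.side_types, .side_types, paste, sep = "_"))
}

# condition evaluation for one side on one column; NA-free logical vector
eval_side <- function(x, type, params, mdr) {
  cls <- classify_cells(x, mdr)
  switch(type,
    set = {
      vals <- normalize_code(as.character(x))
      cls == "observed" & !is.na(vals) & vals %in% parse_value_set(params)
    },
    range = {
      v <- suppressWarnings(as.numeric(as.character(x)))
      iv <- parse_interval(params)
      cls == "observed" & !is.na(v) & in_interval(v, iv)
    },
    trange = {
      v <- parse_iso_datetime(as.character(x))
      iv <- parse_interval(params, type = "datetime")
      cls == "observed" & !is.na(v) & in_interval(v, iv)
    },
    miss = {
      hit <- cls %in% c("missing_code", "jump_code")
      if (!is.na(params) && trimws(params) != "") {
        hit & normalize_code(as.character(x)) %in% parse_value_set(params)
      } else hit
    },
    stop("unknown side condition type: ", sQuote(type), call. = FALSE)
  )
}

parse_value_set <- function(params) {
  normalize_code(trimws(strsplit(as.character(params), "|", fixed = TRUE)[[1]]))
}

#' Construct and validate a contradiction rule table
#'
#' @param rules Data frame with columns `rule_id`, `predicate_code`,
#'   `var_a`, `params_a`, `var_b`, `params_b`, `class` (`logical` or
#'   `empirical`) and optional `label`.
#' @return A validated `dq_rules` tibble.
#' @export
dq_rules <- function(rules) {
  rules <- tibble::as_tibble(rules)
  needed <- c("rule_id", "predicate_code", "var_a", "params_a", "var_b", "params_b", "class")
  miss <- setdiff(needed, names(rules))
  if (length(miss)) stop("rule table lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"label" %in% names(rules)) rules$label <- rules$rule_id
  bad <- !rules$predicate_code %in% dq_predicates()
  if (any(bad)) stop("unknown predicate code(s): ",
                     paste(unique(rules$predicate_code[bad]), collapse = ", "),
                     call. = FALSE)
  if (any(rules$var_a == rules$var_b)) {
    stop("contradiction rules must compare two distinct variables", call. = FALSE)
  }
  if (!all(rules$class %in% c("logical", "empirical"))) {
    stop("rule class must be 'logical' or 'empirical'", call. = FALSE)
  }
  class(rules) <- unique(c("dq_rules", class(rules)))
  rules
}

#' @rdname dq_rules
#' @param path Path to a delimited rule file.
#' @export
read_dq_rules <- function(path) dq_rules(read_delim_auto(path))

#' Contradictions between pairs of data values
#'
#' Evaluates each rule of a [dq_rules()] table and counts, per rule, the
#' observational units where both side conditions hold. Results are split by
#' rule class into logically impossible combinations (DQI-3008) and
#' combinations deemed impossible on empirical grounds (DQI-3009). A rule
#' referencing an unknown variable is skipped with a warning rather than
#' failing the run.
#'
#' @param study Study data frame.
#' @param rules A [dq_rules()] table.
#' @param metadata A [dq_metadata()] table (code-aware evaluation).
#' @param id_var Identifier column.
#' @return A `dq_result` tibble with one row per evaluated rule; `variable`
#'   holds the rule id, the descriptor the variable pair and label.
#' @export
contradictions <- function(study, rules, metadata = NULL, id_var = "id") {
  rules <- dq_rules(rules)
  ids <- record_ids(study, id_var)
  rows <- purrr::pmap(rules, function(rule_id, predicate_code, var_a, params_a,
                                      var_b, params_b, class, label, ...) {
    if (!var_a %in% names(study) || !var_b %in% names(study)) {
      warning("rule ", rule_id, " references unknown variable(s); skipped",
              call. = FALSE)
      return(NULL)
    }
    types <- strsplit(predicate_code, "_", fixed = TRUE)[[1]]
    mdr_a <- if (!is.null(metadata)) md_row(metadata, var_a) else NULL
    mdr_b <- if (!is.null(metadata)) md_row(metadata, var_b) else NULL
    fire <- eval_side(study[[var_a]], types[1], params_a, mdr_a) &
      eval_side(study[[var_b]], types[2], params_b, mdr_b)
    dq_result_row(
      if (class == "logical") "DQI-3008" else "DQI-3009",
      rule_id, n_flagged = sum(fire), denominator = nrow(study),
      flagged = cells(ids[fire], var_a),
      descriptor = list(var_a = var_a, var_b = var_b, label = label,
                        predicate = predicate_code, class = class),
      subclass = "dq_contradictions")
  })
  rows <- purrr::compact(rows)
  as_dq_result(bind_dq_results(rows), "dq_contradictions")
}
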