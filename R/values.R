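# Cell-level value classification and type probing shared by all checks.

# Classify each cell of a column as observed / system-missing / coded-missing
# / jump, given one variable's metadata (may be NULL).
classify_cells <- function(x, mdr = NULL) {
  chr <- as.character(x)
  out <- rep("observed", length(x))
  out[is.na(chr) | trimws(chr) == ""] <- "system"
  if (!is.null(mdr)) {
    code_chr <- normalize_code(chr)
    if (length(mdr$missing_codes)) {
      out[out == "observed" & code_chr %in% names(mdr$missing_codes)] <- "missing_code"
    }
    if (length(mdr$jump_codes)) {
      out[out == "observed" & code_chr %in% names(mdr$jump_codes)] <- "jump_code"
    }
  }
  out
}

# "99901", "99901.0", 99901 -> "99901"; non-integers keep their text form
normalize_code <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  ifelse(!is.na(v) & v == round(v), format(round(v), scientific = FALSE, trim = TRUE),
         as.character(x))
}

is_missing_any <- function(x, mdr = NULL) classify_cells(x, mdr) != "observed"

# observed numeric values with qualified codes stripped; keeps positions
observed_numeric <- function(x, mdr = NULL) {
  cls <- classify_cells(x, mdr)
  idx <- which(cls == "observed")
  vals <- suppressWarnings(as.numeric(as.character(x)[idx]))
  keep <- !is.na(vals)
  list(values = vals[keep], idx = idx[keep])
}

# --- type probing -----------------------------------------------------------

is_integer_text <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  !is.na(num) & num == round(num) & abs(num) < 2^53 &
    grepl("^\\s*[-+]?\\d+\\s*$", v)
}

is_float_text <- function(v) {
  !is.na(suppressWarnings(as.numeric(v)))
}

is_datetime_text <- function(v) {
  !is.na(parse_iso_datetime(v))
}

# Conservative probing order: integer -> float -> datetime -> string.
# A column is "integer" only if every non-missing value converts losslessly.
probe_type <- function(x, mdr = NULL) {
  cls <- classify_cells(x, mdr)
  v <- as.character(x)[cls == "observed"]
  if (length(v) == 0) return(NA_character_)
  if (all(is_integer_text(v))) return("integer")
  if (all(is_float_text(v))) return("float")
  if (all(is_datetime_text(v))) return("datetime")
  "string"
}

# Per-cell convertibility to an expected type (observed cells only; missing
# and qualified-coded cells are "skipped").
cell_type_verdicts <- function(x, expected, mdr = NULL) {
  if (!expected %in% c("integer", "float", "string", "datetime")) {
    stop("unknown expected data type: ", sQuote(expected), call. = FALSE)
  }
  cls <- classify_cells(x, mdr)
  v <- as.character(x)
  ok <- switch(expected,
    integer = is_integer_text(v),
    float = is_float_text(v),
    datetime = is_datetime_text(v),
    string = rep(TRUE, length(v))
  )
  verdict <- ifelse(cls != "observed", "skipped",
                    ifelse(ok, "convertible", "unconvertible"))
  verdict
}

#' Check a column's values against an expected data type
#'
#' Classifies every observed (non-missing, non-coded) cell as convertible or
#' not to the expected type. Integer conversion must be lossless (`"1.5"`
#' does not convert to integer); date-time values must be valid ISO-8601
#' calendar dates (`"2001-02-30"` does not convert).
#'
#' @param x A vector of raw cell values.
#' @param expected One of `"integer"`, `"float"`, `"string"`, `"datetime"`.
#' @param max_fail_fraction Column verdict is `"mismatch"` when the fraction
#'   of unconvertible observed cells exceeds this (default 0: any
#'   unconvertible cell).
#' @param metadata Optional `dq_metadata`; declared missing/jump codes are
#'   skipped, and `var` selects the row.
#' @param var Variable name within `metadata`.
#' @return A list with `verdicts` (per-cell: convertible / unconvertible /
#'   skipped) and `column` (`"match"` or `"mismatch"`).
#' @export
check_data_type <- function(x, expected, max_fail_fraction = 0,
                            metadata = NULL, var = NULL) {
  mdr <- if (!is.null(metadata) && !is.null(var)) md_row(metadata, var) else NULL
  verdicts <- cell_type_verdicts(x, expected, mdr)
  n_obs <- sum(verdicts != "skipped")
  n_bad <- sum(verdicts == "unconvertible")
  column <- if (n_obs > 0 && n_bad / n_obs > max_fail_fraction) "mismatch" else "match"
  list(verdicts = verdicts, column = column,
       n_unconvertible = n_bad, n_observed = n_obs)
}

record_ids <- function(study, id_var) {
  if (!id_var %in% names(study)) {
    stop("identifier variable ", sQuote(id_var), " not found in study data",
         call. = FALSE)
  }
  as.character(study[[id_var]])
}

# names of variables with a given role, present in the study data
vars_with_role <- function(metadata, study, roles = "measurement") {
  intersect(metadata$var_name[metadata$role %in% roles], names(study))
}
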