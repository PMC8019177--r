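#' Item-level metadata tables
#'
#' Checks are driven by a flat item-level metadata table with one row per
#' variable and the columns
#' `VAR_NAMES`, `LABEL`, `DATA_TYPE`, `HARD_LIMITS`, `SOFT_LIMITS`,
#' `DETECTION_LIMITS`, `VALUE_LABELS`, `MISSING_LIST`, `JUMP_LIST`,
#' `STUDY_SEGMENT`, `KEY_OBSERVER`, `KEY_DATETIME`, and optionally `ROLE`
#' and `SOURCE_TABLE`. Only `VAR_NAMES` and `DATA_TYPE` are mandatory.
#'
#' Limits are interval literals (see [parse_interval()]). `VALUE_LABELS`,
#' `MISSING_LIST` and `JUMP_LIST` hold `code = label` pairs separated by
#' `|` (e.g. `"1 = yes | 2 = no"`); missing and jump codes are integers,
#' conventionally >= 99900 so they cannot collide with measurements.
#' `KEY_OBSERVER`/`KEY_DATETIME` name the process variable (examiner ID,
#' examination timestamp) attached to a measurement. A variable's `role` is
#' taken from `ROLE` when given, otherwise inferred: variables referenced by
#' any `KEY_OBSERVER` become `process-examiner`, by `KEY_DATETIME`
#' `process-time`; everything else is a `measurement`.
#'
#' @param md A data frame in the column vocabulary above.
#' @param id_var Optional name of the record identifier variable; it is
#'   assigned the `identifier` role.
#' @return A `dq_metadata` tibble with parsed list columns
#'   (`hard_limits`, `soft_limits`, `detection_limits` as `dq_interval`s;
#'   `categories`, `missing_codes`, `jump_codes` as named character vectors
#'   mapping code to label).
#' @examples
#' md <- data.frame(VAR_NAMES = "sbp", DATA_TYPE = "float",
#'                  HARD_LIMITS = "[60;300]", MISSING_LIST = "99901 = refusal")
#' dq_metadata(md)
#' @export
dq_metadata <- function(md, id_var = NULL) {
  md <- as.data.frame(md, stringsAsFactors = FALSE)
  required <- c("VAR_NAMES", "DATA_TYPE")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    stop("metadata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(md) == 0) {
    warning("empty metadata table", call. = FALSE)
  }
  opt <- function(col) if (col %in% names(md)) as.character(md[[col]]) else rep(NA_character_, nrow(md))
  var_name <- as.character(md$VAR_NAMES)
  if (anyNA(var_name) || any(var_name == "")) {
    stop("metadata has empty VAR_NAMES entries", call. = FALSE)
  }
  if (anyDuplicated(var_name)) {
    stop("duplicate VAR_NAMES in metadata: ",
         paste(unique(var_name[duplicated(var_name)]), collapse = ", "),
         call. = FALSE)
  }
  data_type <- tolower(as.character(md$DATA_TYPE))
  bad_type <- !data_type %in% c("integer", "float", "string", "datetime")
  if (any(bad_type)) {
    stop("unknown DATA_TYPE for variable(s): ",
         paste(var_name[bad_type], collapse = ", "),
         " (must be integer, float, string or datetime)", call. = FALSE)
  }

  itype <- ifelse(data_type == "datetime", "datetime", "numeric")
  parse_lim <- function(col) {
    purrr::map2(opt(col), itype, function(lit, ty) {
      if (is.na(lit) || trimws(lit) == "") return(NULL)
      tryCatch(parse_interval(lit, type = ty),
               error = function(e) {
                 warning("ignoring unparseable ", col, " entry ", sQuote(lit),
                         ": ", conditionMessage(e), call. = FALSE)
                 NULL
               })
    })
  }

  out <- tibble::tibble(
    var_name = var_name,
    label = dplyr::coalesce(opt("LABEL"), var_name),
    data_type = data_type,
    hard_limits = parse_lim("HARD_LIMITS"),
    soft_limits = parse_lim("SOFT_LIMITS"),
    detection_limits = parse_lim("DETECTION_LIMITS"),
    categories = purrr::map(opt("VALUE_LABELS"), parse_code_map),
    missing_codes = purrr::map(opt("MISSING_LIST"), parse_code_map),
    jump_codes = purrr::map(opt("JUMP_LIST"), parse_code_map),
    segment = opt("STUDY_SEGMENT"),
    key_observer = opt("KEY_OBSERVER"),
    key_datetime = opt("KEY_DATETIME"),
    source_table = opt("SOURCE_TABLE"),
    role = opt("ROLE")
  )

  # soft limits must sit inside hard limits
  bad <- purrr::map2_lgl(out$hard_limits, out$soft_limits, function(h, s) {
    !is.null(h) && !is.null(s) && !interval_contains(h, s)
  })
  if (any(bad)) {
    stop("soft limits not contained in hard limits for variable(s): ",
         paste(out$var_name[bad], collapse = ", "), call. = FALSE)
  }
  # missing/jump codes must be disjoint from admissible categories
  clash <- purrr::pmap_lgl(out[c("categories", "missing_codes", "jump_codes")],
                           function(categories, missing_codes, jump_codes) {
    codes <- c(names(missing_codes), names(jump_codes))
    length(intersect(codes, names(categories))) > 0 ||
      anyDuplicated(codes) > 0
  })
  if (any(clash)) {
    stop("missing/jump codes overlap admissible categories for variable(s): ",
         paste(out$var_name[clash], collapse = ", "), call. = FALSE)
  }

  # role inference
  infer <- rep("measurement", nrow(out))
  infer[out$var_name %in% stats::na.omit(out$key_observer)] <- "process-examiner"
  infer[out$var_name %in% stats::na.omit(out$key_datetime)] <- "process-time"
  if (!is.null(id_var)) infer[out$var_name == id_var] <- "identifier"
  out$role <- ifelse(is.na(out$role), infer, out$role)
  bad_role <- !out$role %in% c("measurement", "process-examiner", "process-device",
                               "process-time", "identifier")
  if (any(bad_role)) {
    stop("unknown ROLE for variable(s): ",
         paste(out$var_name[bad_role], collapse = ", "), call. = FALSE)
  }

  class(out) <- unique(c("dq_metadata", class(out)))
  out
}

#' @rdname dq_metadata
#' @param path Path to a delimited metadata file (CSV or TSV, UTF-8; the
#'   delimiter is auto-detected).
#' @export
read_dq_metadata <- function(path, id_var = NULL) {
  dq_metadata(read_delim_auto(path), id_var = id_var)
}

# "1 = yes | 2 = no" -> c(`1` = "yes", `2` = "no"); bare codes get themselves
# as label. Empty/NA -> NULL.
parse_code_map <- function(text) {
  if (is.na(text) || trimws(text) == "") return(NULL)
  parts <- trimws(strsplit(text, "|", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  if (length(parts) == 0) return(NULL)
  kv <- strsplit(parts, "=", fixed = TRUE)
  codes <- trimws(vapply(kv, `[`, "", 1))
  labels <- trimws(vapply(kv, function(p) if (length(p) >= 2) paste(p[-1], collapse = "=") else p[1], ""))
  stats::setNames(labels, codes)
}

format_code_map <- function(map) {
  if (is.null(map) || length(map) == 0) return(NA_character_)
  paste(paste(names(map), "=", map), collapse = " | ")
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, col_types = readr::cols(.default = "c"))
}

# one variable's metadata as a plain list (list columns unwrapped)
md_row <- function(metadata, var) {
  i <- match(var, metadata$var_name)
  if (is.na(i)) return(NULL)
  row <- as.list(metadata[i, ])
  lapply(row, function(v) if (is.list(v)) v[[1]] else v)
}

# all declared qualified codes (missing + jump) for one metadata row,
# as a character vector of code strings
qualified_codes <- function(mdr) {
  c(names(mdr$missing_codes), names(mdr$jump_codes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
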