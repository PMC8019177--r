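#' Interval grammar for admissibility limits
#'
#' Hard, soft and detection limits are written as interval literals of the
#' form `"[0;200]"`, `"(0;Inf)"` or `"[2001-01-01;2001-12-31]"`. The bracket
#' characters encode closedness (`[`/`]` closed, `(`/`)` open), `;` separates
#' the endpoints (avoiding decimal-comma ambiguity), `-Inf`/`Inf` denote
#' unbounded endpoints, and ISO-8601 timestamps are accepted for date-time
#' variables.
#'
#' @param text A single interval literal string.
#' @param type `"numeric"` or `"datetime"`; controls endpoint parsing.
#' @return A `dq_interval` object: a list with `lower`, `upper`,
#'   `lower_closed`, `upper_closed` and `type`.
#' @examples
#' parse_interval("[0;200]")
#' parse_interval("(0;Inf)")
#' in_interval(c(0, 100, 200), parse_interval("[0;200)"))
#' @export
parse_interval <- function(text, type = c("numeric", "datetime")) {
  type <- match.arg(type)
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^([\\[(])\\s*([^;]*?)\\s*;\\s*([^;]*?)\\s*([\\])])$",
                               txt, perl = TRUE))[[1]]
  if (length(m) != 5L) {
    stop("malformed interval literal: ", sQuote(text),
         " (expected e.g. \"[0;200]\" or \"(0;Inf)\")", call. = FALSE)
  }
  lo <- .parse_endpoint(m[3], type, text)
  hi <- .parse_endpoint(m[4], type, text)
  lower_closed <- m[2] == "["
  upper_closed <- m[5] == "]"
  if (as.numeric(lo) > as.numeric(hi)) {
    stop("invalid interval ", sQuote(text), ": lower > upper", call. = FALSE)
  }
  if (as.numeric(lo) == as.numeric(hi) && !(lower_closed && upper_closed)) {
    stop("invalid interval ", sQuote(text), ": empty (open endpoints at equal bounds)",
         call. = FALSE)
  }
  new_dq_interval(lo, hi, lower_closed, upper_closed, type)
}

.parse_endpoint <- function(tok, type, literal) {
  if (tok %in% c("Inf", "+Inf")) return(Inf)
  if (tok == "-Inf") return(-Inf)
  if (tok == "") {
    stop("malformed interval literal: ", sQuote(literal),
         " (empty endpoint token)", call. = FALSE)
  }
  if (type == "datetime") {
    out <- parse_iso_datetime(tok)
    if (is.na(out)) {
      stop("malformed interval literal: ", sQuote(literal),
           " (unparseable timestamp ", sQuote(tok), ")", call. = FALSE)
    }
    return(as.numeric(out))
  }
  out <- suppressWarnings(as.numeric(tok))
  if (is.na(out)) {
    stop("malformed interval literal: ", sQuote(literal),
         " (unparseable number ", sQuote(tok), ")", call. = FALSE)
  }
  out
}

new_dq_interval <- function(lower, upper, lower_closed, upper_closed,
                            type = "numeric") {
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         lower_closed = lower_closed, upper_closed = upper_closed,
         type = type),
    class = "dq_interval"
  )
}

#' @export
format.dq_interval <- function(x, ...) {
  fmt1 <- function(v) {
    if (is.infinite(v)) return(ifelse(v > 0, "Inf", "-Inf"))
    if (x$type == "datetime") return(format(as.POSIXct(v, origin = "1970-01-01", tz = "UTC"),
                                            "%Y-%m-%dT%H:%M:%S"))
    format(v, scientific = FALSE, trim = TRUE)
  }
  paste0(if (x$lower_closed) "[" else "(", fmt1(x$lower), ";", fmt1(x$upper),
         if (x$upper_closed) "]" else ")")
}

#' @export
print.dq_interval <- function(x, ...) {
  cat("<dq_interval ", format(x), if (x$type == "datetime") " (datetime)", ">\n", sep = "")
  invisible(x)
}

#' Interval membership
#'
#' Decides membership for each value, respecting endpoint closedness: for
#' `"[0;200)"`, 0 is inside and 200 is outside. `NA` values yield `NA`.
#'
#' @param x Numeric (or POSIXct) vector.
#' @param interval A `dq_interval`.
#' @return Logical vector the length of `x`.
#' @export
in_interval <- function(x, interval) {
  stopifnot(inherits(interval, "dq_interval"))
  v <- as.numeric(x)
  lo <- if (interval$lower_closed) v >= interval$lower else v > interval$lower
  hi <- if (interval$upper_closed) v <= interval$upper else v < interval$upper
  lo & hi
}

#' @rdname in_interval
#' @param inner,outer Two `dq_interval` objects.
#' @details `interval_contains(outer, inner)` is `TRUE` when every point of
#'   `inner` lies in `outer` (used to validate that soft limits sit inside
#'   hard limits).
#' @export
interval_contains <- function(outer, inner) {
  lo_ok <- inner$lower > outer$lower ||
    (inner$lower == outer$lower && (outer$lower_closed || !inner$lower_closed))
  hi_ok <- inner$upper < outer$upper ||
    (inner$upper == outer$upper && (outer$upper_closed || !inner$upper_closed))
  lo_ok && hi_ok
}

# Strict ISO-8601 parsing: "YYYY-MM-DD" or "YYYY-MM-DDTHH:MM:SS" (space also
# accepted). Returns POSIXct (UTC) or NA; impossible calendar dates are NA.
parse_iso_datetime <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.POSIXct(NA), length(x))
  date_re <- "^\\d{4}-\\d{2}-\\d{2}$"
  dt_re <- "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$"
  is_d <- !is.na(x) & grepl(date_re, x)
  is_dt <- !is.na(x) & grepl(dt_re, x)
  if (any(is_d)) {
    p <- as.POSIXct(strptime(x[is_d], "%Y-%m-%d", tz = "UTC"))
    # strptime validates the calendar, but double-check round-trip to reject
    # any rolled-over dates (e.g. 2001-02-30)
    ok <- !is.na(p) & format(p, "%Y-%m-%d") == x[is_d]
    p[!ok] <- NA
    out[is_d] <- p
  }
  if (any(is_dt)) {
    xx <- sub("T", " ", x[is_dt], fixed = TRUE)
    xx <- ifelse(grepl(":\\d{2}:\\d{2}$", xx), xx, paste0(xx, ":00"))
    p <- as.POSIXct(strptime(xx, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    ok <- !is.na(p) & format(p, "%Y-%m-%d %H:%M:%S") == xx
    p[!ok] <- NA
    out[is_dt] <- p
  }
  out
}
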