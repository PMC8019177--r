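#' Indicator result tibbles
#'
#' Every check in the package returns a `dq_result`: a tibble with one row
#' per (indicator, variable) outcome. Columns:
#' \describe{
#'   \item{indicator_id}{DQI code, a member of [dq_registry()].}
#'   \item{variable}{variable name, or `"study-level"` for study-wide checks.}
#'   \item{n_flagged}{number of issues found.}
#'   \item{denominator}{number of assessed elements.}
#'   \item{percent}{`100 * n_flagged / denominator`, `NA` when the
#'     denominator is zero.}
#'   \item{grading}{`"ok"`, `"issue"` or `"not-applicable"`.}
#'   \item{flagged}{list column of tibbles with `record_id` and `var_name`
#'     cell coordinates (empty for record- or study-level findings).}
#'   \item{descriptor}{list column carrying non-machine-readable payloads
#'     (binned counts, smoothed series, level tables); `NULL` where a check
#'     produces none.}
#' }
#'
#' @param indicator_id,variable,n_flagged,denominator See description.
#' @param flagged A tibble of `(record_id, var_name)` coordinates, or `NULL`.
#' @param descriptor An arbitrary structured payload, or `NULL`.
#' @param grading Override the default grading (issue iff `n_flagged > 0`).
#' @param subclass Optional extra S3 class prepended for plot dispatch.
#' @return A one-row `dq_result` tibble.
#' @keywords internal
#' @export
dq_result_row <- function(indicator_id, variable, n_flagged, denominator,
                          flagged = NULL, descriptor = NULL,
                          grading = NULL, subclass = NULL) {
  if (is.null(flagged)) flagged <- empty_cells()
  if (is.null(grading)) {
    grading <- if (n_flagged > 0) "issue" else "ok"
  }
  out <- tibble::tibble(
    indicator_id = indicator_id,
    variable = variable,
    n_flagged = as.integer(n_flagged),
    denominator = as.integer(denominator),
    percent = ifelse(denominator > 0, 100 * n_flagged / denominator, NA_real_),
    grading = grading,
    flagged = list(flagged),
    descriptor = list(descriptor)
  )
  as_dq_result(out, subclass)
}

as_dq_result <- function(x, subclass = NULL) {
  class(x) <- unique(c(subclass, "dq_result", class(tibble::tibble())))
  x
}

empty_cells <- function() {
  tibble::tibble(record_id = character(), var_name = character())
}

cells <- function(record_id, var_name) {
  tibble::tibble(record_id = as.character(record_id),
                 var_name = rep_len(var_name, length(record_id)))
}

#' @export
print.dq_result <- function(x, ...) {
  cat("# Data quality indicator result", "\n")
  NextMethod()
}

# bind results preserving the dq_result class
bind_dq_results <- function(...) {
  out <- dplyr::bind_rows(...)
  as_dq_result(out)
}
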