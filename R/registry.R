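#' The data quality indicator registry
#'
#' The framework distinguishes 34 data quality indicators across four
#' dimensions: *integrity* (compliance with structural and technical
#' requirements), *completeness* (presence of expected data values),
#' *consistency* (inadmissible or uncertain values and contradictory value
#' combinations) and *accuracy* (unexpected distributions and associations).
#' Each dimension groups indicators into domains that differ by the
#' methodology used (e.g. crude vs. qualified missingness).
#'
#' Indicators for standardized-vocabulary violations, value precision,
#' association strength/direction/form, intra-class reliability and
#' gold-standard disagreement are registered but not implemented by any
#' check in this package; their `implemented` flag is `FALSE`.
#'
#' @return A tibble with columns `id`, `name`, `dimension`, `domain` and
#'   `implemented`; always 34 rows, identical across calls.
#' @examples
#' dq_registry()
#' dplyr::count(dq_registry(), dimension)
#' @export
dq_registry <- function() {
  tibble::tribble(
    ~id, ~name, ~dimension, ~domain, ~implemented,
    "DQI-1001", "Unexpected data elements",            "integrity", "structural data set error", TRUE,
    "DQI-1002", "Unexpected data records",             "integrity", "structural data set error", TRUE,
    "DQI-1003", "Duplicates",                          "integrity", "structural data set error", TRUE,
    "DQI-1004", "Data record mismatch",                "integrity", "relational data set error", TRUE,
    "DQI-1005", "Data element mismatch",               "integrity", "relational data set error", TRUE,
    "DQI-1006", "Data type mismatch",                  "integrity", "value format error", TRUE,
    "DQI-1007", "Inhomogeneous value formats",         "integrity", "value format error", TRUE,
    "DQI-1008", "Uncertain missingness status",        "integrity", "value format error", TRUE,
    "DQI-2001", "Missing values",                      "completeness", "crude missingness", TRUE,
    "DQI-2002", "Non-response rate",                   "completeness", "qualified missingness", TRUE,
    "DQI-2003", "Refusal rate",                        "completeness", "qualified missingness", TRUE,
    "DQI-2004", "Drop-out rate",                       "completeness", "qualified missingness", TRUE,
    "DQI-2005", "Missing due to specified reason",     "completeness", "qualified missingness", TRUE,
    "DQI-3001", "Inadmissible numerical values",       "consistency", "range and value violations", TRUE,
    "DQI-3002", "Inadmissible time-date values",       "consistency", "range and value violations", TRUE,
    "DQI-3003", "Inadmissible categorical values",     "consistency", "range and value violations", TRUE,
    "DQI-3004", "Inadmissible standardized vocabulary","consistency", "range and value violations", FALSE,
    "DQI-3005", "Inadmissible precision",              "consistency", "range and value violations", FALSE,
    "DQI-3006", "Uncertain numerical values",          "consistency", "range and value violations", TRUE,
    "DQI-3007", "Uncertain time-date values",          "consistency", "range and value violations", TRUE,
    "DQI-3008", "Logical contradictions",              "consistency", "contradictions", TRUE,
    "DQI-3009", "Empirical contradictions",            "consistency", "contradictions", TRUE,
    "DQI-4001", "Univariate outliers",                 "accuracy", "unexpected distributions", TRUE,
    "DQI-4002", "Multivariate outliers",               "accuracy", "unexpected distributions", TRUE,
    "DQI-4003", "Unexpected locations",                "accuracy", "unexpected distributions", TRUE,
    "DQI-4004", "Unexpected shape",                    "accuracy", "unexpected distributions", TRUE,
    "DQI-4005", "Unexpected scale",                    "accuracy", "unexpected distributions", TRUE,
    "DQI-4006", "Unexpected proportions",              "accuracy", "unexpected distributions", TRUE,
    "DQI-4007", "Unexpected association strength",     "accuracy", "unexpected associations", FALSE,
    "DQI-4008", "Unexpected association direction",    "accuracy", "unexpected associations", FALSE,
    "DQI-4009", "Unexpected association form",         "accuracy", "unexpected associations", FALSE,
    "DQI-4010", "Inter-class reliability",             "accuracy", "disagreement of repeated measurements", TRUE,
    "DQI-4011", "Intra-class reliability",             "accuracy", "disagreement of repeated measurements", FALSE,
    "DQI-4012", "Disagreement with gold standard",     "accuracy", "disagreement of repeated measurements", FALSE
  )
}
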