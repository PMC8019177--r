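# Univariate and multivariate outlier detection.
#
# Four univariate rules are implemented; all quantiles use linear
# interpolation (type 7) so fences are reproducible across implementations:
#   tukey     outside [Q1 - 1.5*IQR, Q3 + 1.5*IQR]
#   sixsigma  outside mean +/- 3*SD (total width six sigma)
#   hubert    skewness-adjusted fences driven by the medcouple MC:
#             [Q1 - 1.5*exp(-4*MC)*IQR, Q3 + 1.5*exp(3*MC)*IQR] for MC >= 0,
#             exponents mirrored for MC < 0 (reduces to tukey when MC = 0)
#   mad       outside median +/- 3*MAD (MAD scaled by 1.4826)

#' Names of the univariate outlier rules
#' @return `c("tukey", "sixsigma", "hubert", "mad")`
#' @export
dq_outlier_rules <- function() c("tukey", "sixsigma", "hubert", "mad")

#' Medcouple, a robust skewness measure
#'
#' Exact O(n^2) kernel evaluation: for all pairs \eqn{x_i \le m \le x_j}
#' around the median \eqn{m}, the kernel
#' \eqn{h = ((x_j - m) - (m - x_i)) / (x_j - x_i)} is computed (with the
#' usual sign kernel for observations tied with the median) and its median
#' returned. Zero for symmetric samples, in \[-1, 1\] generally.
#'
#' @param x Numeric vector (NAs dropped).
#' @return The medcouple of `x`.
#' @export
medcouple <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 3) return(0)
  m <- if (n %% 2 == 0) (x[n %/% 2] + x[n %/% 2 + 1]) / 2 else x[(n + 1) %/% 2]
  z <- x - m
  lower <- z[z <= 0]           # ascending, <= 0
  upper <- z[z >= 0]           # ascending, >= 0
  h <- outer(upper, lower, function(u, l) {
    s <- u - l
    ifelse(s == 0, NA_real_, (u + l) / s)
  })
  k <- sum(lower == 0)
  if (k > 0) {
    # sign kernel for observations tied with the median: -1 above the
    # anti-diagonal, 0 on it, +1 below
    rep_block <- matrix(1, k, k) - diag(k)
    rep_block <- rep_block - 2 * upper.tri(rep_block) * rep_block
    rep_block <- rep_block[, rev(seq_len(k)), drop = FALSE]
    h[seq_len(k), (length(lower) - k + 1):length(lower)] <- rep_block
  }
  stats::median(h)
}

#' Outlier fences for one rule
#'
#' @param x Numeric vector (NAs dropped).
#' @param rule One of [dq_outlier_rules()].
#' @return `c(lower, upper)`; values strictly outside are outliers.
#' @export
outlier_fences <- function(x, rule = dq_outlier_rules()) {
  rule <- match.arg(rule)
  x <- x[!is.na(x)]
  switch(rule,
    tukey = {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
    },
    sixsigma = {
      mu <- mean(x); s <- stats::sd(x)
      c(mu - 3 * s, mu + 3 * s)
    },
    hubert = {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      mc <- medcouple(x)
      if (mc >= 0) c(q[1] - 1.5 * exp(-4 * mc) * iqr, q[2] + 1.5 * exp(3 * mc) * iqr)
      else         c(q[1] - 1.5 * exp(-3 * mc) * iqr, q[2] + 1.5 * exp(4 * mc) * iqr)
    },
    mad = {
      med <- stats::median(x)
      m <- stats::mad(x)  # includes the 1.4826 consistency constant
      c(med - 3 * m, med + 3 * m)
    })
}

#' Univariate outliers
#'
#' Applies up to four outlier rules to a numeric variable (qualified codes
#' and hard-limit violations stripped first) and flags values for which at
#' least `threshold` rules fire, reporting the direction (low/high) per
#' value (DQI-4001).
#'
#' @param study Study data frame.
#' @param var Variable to check.
#' @param metadata Optional [dq_metadata()] (code stripping, hard limits).
#' @param id_var Identifier column.
#' @param rules Subset of [dq_outlier_rules()].
#' @param threshold Minimum number of rules that must fire (default 1).
#' @param min_n Minimum non-missing values required (default 10).
#' @return A `dq_result` tibble; the descriptor holds per-value verdicts
#'   (`record_id`, `value`, `rules_fired`, `direction`) and the fences.
#' @examples
#' d <- data.frame(id = 1:11, y = c(1:10, 100))
#' univariate_outliers(d, "y")
#' @export
univariate_outliers <- function(study, var, metadata = NULL, id_var = "id",
                                rules = dq_outlier_rules(), threshold = 1,
                                min_n = 10) {
  rules <- match.arg(rules, several.ok = TRUE)
  mdr <- if (!is.null(metadata)) md_row(metadata, var) else NULL
  ids <- record_ids(study, id_var)
  on <- observed_numeric(study[[var]], mdr)
  vals <- on$values; idx <- on$idx
  if (!is.null(mdr) && !is.null(mdr$hard_limits)) {
    keep <- in_interval(vals, mdr$hard_limits)
    vals <- vals[keep]; idx <- idx[keep]
  }
  if (length(vals) < min_n) {
    return(dq_result_row("DQI-4001", var, 0L, length(vals),
                         grading = "not-applicable",
                         descriptor = list(note = sprintf(
                           "fewer than %d non-missing values", min_n)),
                         subclass = "dq_univariate_outliers"))
  }
  fences <- purrr::map(stats::setNames(rules, rules), ~ outlier_fences(vals, .x))
  fired <- purrr::map(fences, function(f) vals < f[1] | vals > f[2])
  n_fired <- Reduce(`+`, purrr::map(fired, as.integer))
  flag <- n_fired >= threshold
  direction <- ifelse(vals < stats::median(vals), "low", "high")
  verdicts <- tibble::tibble(
    record_id = ids[idx[flag]],
    value = vals[flag],
    rules_fired = purrr::map(which(flag), function(i) {
      rules[vapply(fired, `[`, logical(1), i)]
    }),
    direction = direction[flag]
  )
  dq_result_row("DQI-4001", var,
                n_flagged = sum(flag), denominator = length(vals),
                flagged = cells(ids[idx[flag]], var),
                descriptor = list(verdicts = verdicts, fences = fences,
                                  threshold = threshold),
                subclass = "dq_univariate_outliers")
}

#' Multivariate outliers via Mahalanobis distance
#'
#' Computes the Mahalanobis distance of each complete case from the sample
#' mean and covariance of at least two numeric variables, then applies the
#' univariate outlier rules to the distance vector (high direction only) --
#' a heuristic that keeps the computation cheap (DQI-4002).
#'
#' @param study Study data frame.
#' @param vars Two or more numeric variables.
#' @param metadata Optional [dq_metadata()].
#' @param id_var Identifier column.
#' @param rules,threshold As in [univariate_outliers()].
#' @return A `dq_result` tibble; the descriptor carries the distances.
#' @export
multivariate_outliers <- function(study, vars, metadata = NULL, id_var = "id",
                                  rules = dq_outlier_rules(), threshold = 1) {
  stopifnot(length(vars) >= 2)
  rules <- match.arg(rules, several.ok = TRUE)
  ids <- record_ids(study, id_var)
  cols <- purrr::map(stats::setNames(vars, vars), function(v) {
    mdr <- if (!is.null(metadata)) md_row(metadata, v) else NULL
    cls <- classify_cells(study[[v]], mdr)
    val <- suppressWarnings(as.numeric(as.character(study[[v]])))
    val[cls != "observed"] <- NA
    val
  })
  mat <- do.call(cbind, cols)
  cc <- stats::complete.cases(mat)
  m <- mat[cc, , drop = FALSE]
  S <- stats::cov(m)
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    dependent <- vars[-qrS$pivot[seq_len(qrS$rank)]]
    stop("singular covariance matrix; collinear variable(s): ",
         paste(if (length(dependent)) dependent else vars, collapse = ", "),
         call. = FALSE)
  }
  d2 <- stats::mahalanobis(m, colMeans(m), S)
  d <- sqrt(d2)
  fences <- purrr::map(stats::setNames(rules, rules), ~ outlier_fences(d, .x))
  fired <- purrr::map(fences, function(f) d > f[2])  # high direction only
  n_fired <- Reduce(`+`, purrr::map(fired, as.integer))
  flag <- n_fired >= threshold
  cc_ids <- ids[cc]
  dq_result_row("DQI-4002", paste(vars, collapse = "+"),
                n_flagged = sum(flag), denominator = sum(cc),
                flagged = cells(cc_ids[flag], vars[1]),
                descriptor = list(distances = tibble::tibble(record_id = cc_ids,
                                                             distance = d),
                                  fences = fences),
                subclass = "dq_multivariate_outliers")
}
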