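# Statistical accuracy checks: distributional tests, end-digit preference,
# examiner effects via covariate-adjusted marginal means, variance
# components, and LOESS time trends.

#' Distribution descriptor
#'
#' Pure descriptor (no machine-readable flag): binned counts for numeric
#' variables, level counts for categorical ones, and per-group empirical
#' cumulative distribution functions when a grouping variable is given.
#'
#' @param study Study data frame.
#' @param var Variable to describe.
#' @param group Optional grouping (class) variable.
#' @param metadata Optional [dq_metadata()].
#' @param id_var Identifier column.
#' @return A `dq_result` tibble with an `NA` indicator id and the payload in
#'   its descriptor.
#' @export
distribution_descriptor <- function(study, var, group = NULL, metadata = NULL,
                                    id_var = "id") {
  mdr <- if (!is.null(metadata)) md_row(metadata, var) else NULL
  on <- observed_numeric(study[[var]], mdr)
  payload <- list(variable = var)
  if (length(on$values) > 0 &&
      length(on$values) >= 0.5 * sum(classify_cells(study[[var]], mdr) == "observed")) {
    vals <- on$values
    h <- graphics::hist(vals, plot = FALSE)
    payload$histogram <- list(breaks = h$breaks, counts = h$counts)
    if (!is.null(group) && group %in% names(study)) {
      g <- as.character(study[[group]])[on$idx]
      payload$ecdf <- purrr::imap(split(vals, g), function(v, lev) {
        sv <- sort(v)
        tibble::tibble(x = sv, F = seq_along(sv) / length(sv))
      })
    }
  } else {
    cls <- classify_cells(study[[var]], mdr)
    payload$levels <- as.list(table(as.character(study[[var]])[cls == "observed"]))
  }
  dq_result_row(NA_character_, var, 0L,
                denominator = sum(classify_cells(study[[var]], mdr) == "observed"),
                grading = "ok", descriptor = payload,
                subclass = "dq_distribution")
}

#' Test a distributional assumption (shape or scale)
#'
#' Tests observed measurements against a predefined distribution family
#' (normal, gamma or uniform). Unless fixed parameters are supplied, family
#' parameters are estimated by the method of moments; observed counts are
#' compared with expected counts on equal-probability bins of the fitted
#' distribution via a Pearson chi-square statistic with
#' `df = bins - 1 - #estimated parameters`. Deviations are carried as a
#' hanging-rootogram descriptor (`sqrt(observed) - sqrt(expected)` per bin).
#' Flags as unexpected shape (DQI-4004) and, via its scale parameters, scale
#' (DQI-4005).
#'
#' @param study Study data frame.
#' @param var Numeric variable.
#' @param family `"normal"`, `"gamma"` or `"uniform"`.
#' @param params Optional fixed parameter list (`mean`/`sd`, `shape`/`rate`,
#'   `min`/`max`); when given, no parameters are estimated.
#' @param bins Number of equal-probability bins (default 10).
#' @param alpha Significance level for the grading decision (default 0.05).
#' @param min_n Minimum observed values (default 30).
#' @param metadata,id_var As elsewhere.
#' @return A `dq_result` tibble; descriptor holds `statistic`, `df`,
#'   `p_value`, bin edges, observed/expected counts and rootogram residuals.
#' @export
shape_or_scale <- function(study, var, family = c("normal", "gamma", "uniform"),
                           params = NULL, bins = 10, alpha = 0.05, min_n = 30,
                           metadata = NULL, id_var = "id") {
  family <- match.arg(family)
  mdr <- if (!is.null(metadata)) md_row(metadata, var) else NULL
  x <- observed_numeric(study[[var]], mdr)$values
  if (length(x) < min_n) {
    return(dq_result_row("DQI-4004", var, 0L, length(x),
                         grading = "not-applicable",
                         descriptor = list(note = sprintf(
                           "fewer than %d non-missing values", min_n))))
  }
  n <- length(x)
  mu <- mean(x); s2 <- stats::var(x)
  est <- is.null(params)
  if (est) {
    params <- switch(family,
      normal = list(mean = mu, sd = sqrt(s2)),
      gamma = list(shape = mu^2 / s2, rate = mu / s2),
      uniform = list(min = mu - sqrt(3 * s2), max = mu + sqrt(3 * s2)))
  }
  n_est <- if (est) 2L else 0L
  qfun <- switch(family,
    normal = function(p) stats::qnorm(p, params$mean, params$sd),
    gamma = function(p) stats::qgamma(p, shape = params$shape, rate = params$rate),
    uniform = function(p) stats::qunif(p, params$min, params$max))
  edges <- qfun(seq(0, 1, length.out = bins + 1))
  edges[1] <- -Inf; edges[bins + 1] <- Inf
  obs <- as.vector(table(cut(x, breaks = edges, include.lowest = TRUE)))
  expected <- rep(n / bins, bins)
  statistic <- sum((obs - expected)^2 / expected)
  df <- bins - 1L - n_est
  p_value <- stats::pchisq(statistic, df, lower.tail = FALSE)
  dq_result_row("DQI-4004", var,
                n_flagged = as.integer(p_value < alpha), denominator = 1L,
                grading = if (p_value < alpha) "issue" else "ok",
                descriptor = list(family = family, params = params,
                                  statistic = statistic, df = df,
                                  p_value = p_value, edges = edges,
                                  observed = obs, expected = expected,
                                  rootogram = sqrt(obs) - sqrt(expected)),
                subclass = "dq_shape_or_scale")
}

#' End-digit preference
#'
#' Manually collected measurements often show digit preference (e.g. blood
#' pressure rounded to 0). The final integer digit of each value -- after
#' rounding to the declared precision, default 0 decimals -- is tabulated
#' and tested against a uniform distribution of digits 0..9 with a
#' chi-square goodness-of-fit test (df = 9); a rootogram-style residual
#' vector is the descriptor (DQI-4004).
#'
#' @param study Study data frame.
#' @param var Numeric variable.
#' @param decimals Declared precision; the digit is taken at the last place
#'   after rounding to this many decimals (default 0).
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum number of values (default 50).
#' @param metadata,id_var As elsewhere.
#' @return A `dq_result` tibble; descriptor holds digit counts, the
#'   chi-square statistic, df and p-value.
#' @export
end_digits <- function(study, var, decimals = 0, alpha = 0.05, min_n = 50,
                       metadata = NULL, id_var = "id") {
  mdr <- if (!is.null(metadata)) md_row(metadata, var) else NULL
  x <- observed_numeric(study[[var]], mdr)$values
  if (length(x) < min_n) {
    return(dq_result_row("DQI-4004", var, 0L, length(x),
                         grading = "not-applicable",
                         descriptor = list(note = sprintf(
                           "fewer than %d non-missing values", min_n))))
  }
  digits <- floor(abs(x) * 10^decimals + 0.5) %% 10
  counts <- as.vector(table(factor(digits, levels = 0:9)))
  n <- length(digits)
  expected <- rep(n / 10, 10)
  statistic <- sum((counts - expected)^2 / expected)
  p_value <- stats::pchisq(statistic, df = 9, lower.tail = FALSE)
  dq_result_row("DQI-4004", var,
                n_flagged = as.integer(p_value < alpha), denominator = 1L,
                grading = if (p_value < alpha) "issue" else "ok",
                descriptor = list(digits = stats::setNames(as.list(counts), 0:9),
                                  statistic = statistic, df = 9,
                                  p_value = p_value,
                                  rootogram = sqrt(counts) - sqrt(expected)),
                subclass = "dq_end_digits")
}

#' Examiner/device effects via covariate-adjusted marginal means
#'
#' Compares the marginal distribution of a measurement across the levels of
#' a process variable (examiner, device) after adjusting for covariates. A
#' linear, logistic or Poisson model `response ~ covariates + class` is
#' fitted according to the response type, covariate-adjusted marginal means
#' (probabilities, rates) per class are computed at the covariate means, and
#' classes whose 95% CI excludes the overall adjusted mean are flagged
#' (DQI-4003 for continuous responses, DQI-4006 for proportions).
#'
#' @param study Study data frame.
#' @param response Measurement variable.
#' @param class_var Process variable with >= 2 levels.
#' @param covariates Character vector of adjustment variables (may be empty:
#'   marginal means then equal raw class means in the linear case).
#' @param family `"auto"` (default), `"linear"`, `"logistic"` or
#'   `"poisson"`.
#' @param min_class_size Classes with fewer observations are dropped
#'   (default 10).
#' @param conf_level CI level for the flagging rule (default 0.95).
#' @param metadata,id_var As elsewhere.
#' @return A `dq_margins` result: a `dq_result` row whose descriptor holds
#'   the per-class tibble (`class`, `n`, `estimate`, `lower`, `upper`,
#'   `flagged`) and the overall adjusted mean.
#' @export
margins <- function(study, response, class_var, covariates = character(),
                    family = c("auto", "linear", "logistic", "poisson"),
                    min_class_size = 10, conf_level = 0.95,
                    metadata = NULL, id_var = "id") {
  family <- match.arg(family)
  mdr <- if (!is.null(metadata)) md_row(metadata, response) else NULL
  d <- prepare_model_frame(study, response, class_var, covariates, mdr,
                           min_class_size, metadata)
  if (is.null(d) || length(unique(d$.class)) < 2) {
    return(dq_result_row("DQI-4003", response, 0L, 0L,
                         grading = "not-applicable",
                         descriptor = list(note = "fewer than 2 usable classes"),
                         subclass = "dq_margins"))
  }
  y <- d$.y
  if (family == "auto") {
    family <- if (all(y %in% c(0, 1))) "logistic"
      else if (all(y >= 0 & y == round(y))) "poisson"
      else "linear"
  }
  fml <- stats::as.formula(paste(".y ~", paste(c(covariates, ".class"), collapse = " + ")))
  fit <- tryCatch(
    switch(family,
      linear = stats::lm(fml, data = d),
      logistic = stats::glm(fml, data = d, family = stats::binomial()),
      poisson = stats::glm(fml, data = d, family = stats::poisson())),
    error = function(e) NULL, warning = function(w) {
      # refit, keeping the result despite convergence chatter
      suppressWarnings(switch(family,
        linear = stats::lm(fml, data = d),
        logistic = stats::glm(fml, data = d, family = stats::binomial()),
        poisson = stats::glm(fml, data = d, family = stats::poisson())))
    })
  if (is.null(fit) || (inherits(fit, "glm") && !fit$converged)) {
    return(dq_result_row("DQI-4003", response, 0L, 0L,
                         grading = "not-applicable",
                         descriptor = list(note = "model did not converge"),
                         subclass = "dq_margins"))
  }
  em <- emmeans::emmeans(fit, ".class", type = "response", level = conf_level)
  emdf <- as.data.frame(em)
  est_col <- intersect(c("emmean", "response", "prob", "rate"), names(emdf))[1]
  lcl_col <- intersect(c("lower.CL", "asymp.LCL"), names(emdf))[1]
  ucl_col <- intersect(c("upper.CL", "asymp.UCL"), names(emdf))[1]
  per_class <- tibble::tibble(
    class = as.character(emdf$.class),
    n = as.integer(table(d$.class)[as.character(emdf$.class)]),
    estimate = emdf[[est_col]],
    lower = emdf[[lcl_col]],
    upper = emdf[[ucl_col]])
  overall <- sum(per_class$estimate * per_class$n) / sum(per_class$n)
  per_class$flagged <- overall < per_class$lower | overall > per_class$upper
  indicator <- if (family == "logistic") "DQI-4006" else "DQI-4003"
  dq_result_row(indicator, response,
                n_flagged = sum(per_class$flagged),
                denominator = nrow(per_class),
                descriptor = list(class_var = class_var, family = family,
                                  per_class = per_class, overall = overall,
                                  conf_level = conf_level),
                subclass = "dq_margins")
}

prepare_model_frame <- function(study, response, class_var, covariates, mdr,
                                min_class_size, metadata = NULL) {
  on <- observed_numeric(study[[response]], mdr)
  if (length(on$values) == 0) return(NULL)
  d <- tibble::tibble(.y = on$values,
                      .class = factor(as.character(study[[class_var]])[on$idx]))
  for (cv in covariates) {
    # qualified missing/jump codes in a covariate are missing, not values
    cv_mdr <- if (!is.null(metadata)) md_row(metadata, cv) else NULL
    cv_on <- observed_numeric(study[[cv]], cv_mdr)
    col <- rep(NA_real_, nrow(study))
    col[cv_on$idx] <- cv_on$values
    d[[cv]] <- col[on$idx]
  }
  d <- d[stats::complete.cases(d) & !is.na(d$.class), , drop = FALSE]
  sizes <- table(d$.class)
  keep <- names(sizes)[sizes >= min_class_size]
  d <- d[d$.class %in% keep, , drop = FALSE]
  d$.class <- droplevels(d$.class)
  if (nrow(d) == 0) NULL else d
}

#' Variance components / intra-class correlation across process classes
#'
#' Decomposes the variance of a continuous measurement into between-class
#' and within-class components with a random-intercept model
#' (`response ~ covariates + (1 | class)`) and reports the intra-class
#' correlation `ICC = s2_between / (s2_between + s2_within)`, the share of
#' total variance explained by examiners/devices (DQI-4010, unexpected
#' location screening DQI-4003). Flagged when the ICC exceeds `threshold`.
#'
#' @inheritParams margins
#' @param threshold ICC above which the result is graded an issue
#'   (default 0.05).
#' @return A `dq_result` row; descriptor holds `icc`, `sigma2_between`,
#'   `sigma2_within` and the class count.
#' @export
varcomp <- function(study, response, class_var, covariates = character(),
                    threshold = 0.05, min_class_size = 10,
                    metadata = NULL, id_var = "id") {
  mdr <- if (!is.null(metadata)) md_row(metadata, response) else NULL
  d <- prepare_model_frame(study, response, class_var, covariates, mdr,
                           min_class_size, metadata)
  if (is.null(d) || length(unique(d$.class)) < 2) {
    return(dq_result_row("DQI-4010", response, 0L, 0L,
                         grading = "not-applicable",
                         descriptor = list(note = "fewer than 2 usable classes"),
                         subclass = "dq_varcomp"))
  }
  fml <- stats::as.formula(paste(".y ~", paste(c(covariates, "(1 | .class)"),
                                               collapse = " + ")))
  fit <- tryCatch(lme4::lmer(fml, data = d, REML = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(dq_result_row("DQI-4010", response, 0L, 0L,
                         grading = "not-applicable",
                         descriptor = list(note = "mixed model failed to fit"),
                         subclass = "dq_varcomp"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_b <- vc$vcov[vc$grp == ".class"]
  s2_w <- vc$vcov[vc$grp == "Residual"]
  icc <- s2_b / (s2_b + s2_w)
  dq_result_row("DQI-4010", response,
                n_flagged = as.integer(icc > threshold), denominator = 1L,
                grading = if (icc > threshold) "issue" else "ok",
                descriptor = list(icc = icc, sigma2_between = s2_b,
                                  sigma2_within = s2_w,
                                  n_classes = length(unique(d$.class)),
                                  threshold = threshold),
                subclass = "dq_varcomp")
}

#' LOESS-smoothed time trends per class
#'
#' Descriptor of measurement drift: raw measurements are adjusted for
#' covariates (residuals of `response ~ covariates`, or centered values
#' without covariates) and the residuals smoothed over examination time per
#' class with LOESS (span 0.75, degree 2), evaluated on a 100-point time
#' grid. No machine-readable flag is produced.
#'
#' @inheritParams margins
#' @param time_var Process time variable (ISO-8601 date/time or numeric).
#' @param span,degree,grid_n LOESS parameters.
#' @param min_points Minimum points per smoothed series (default 30).
#' @return A `dq_result` row with the per-class smoothed series in its
#'   descriptor.
#' @export
loess_trend <- function(study, response, time_var, class_var = NULL,
                        covariates = character(), span = 0.75, degree = 2,
                        grid_n = 100, min_points = 30,
                        metadata = NULL, id_var = "id") {
  mdr <- if (!is.null(metadata)) md_row(metadata, response) else NULL
  on <- observed_numeric(study[[response]], mdr)
  traw <- as.character(study[[time_var]])[on$idx]
  tnum <- suppressWarnings(as.numeric(traw))
  if (all(is.na(tnum))) tnum <- as.numeric(parse_iso_datetime(traw))
  keep <- !is.na(tnum)
  y <- on$values[keep]; tnum <- tnum[keep]
  cl <- if (!is.null(class_var)) as.character(study[[class_var]])[on$idx][keep]
        else rep("all", length(y))
  if (length(unique(tnum)) < 2) {
    return(dq_result_row(NA_character_, response, 0L, length(y),
                         grading = "not-applicable",
                         descriptor = list(note = "degenerate time variable"),
                         subclass = "dq_loess"))
  }
  resid <- if (length(covariates) > 0) {
    d <- tibble::tibble(.y = y)
    for (cv in covariates) {
      cv_mdr <- if (!is.null(metadata)) md_row(metadata, cv) else NULL
      cv_on <- observed_numeric(study[[cv]], cv_mdr)
      col <- rep(NA_real_, nrow(study))
      col[cv_on$idx] <- cv_on$values
      d[[cv]] <- col[on$idx][keep]
    }
    cc <- stats::complete.cases(d)
    r <- rep(NA_real_, length(y))
    fit <- stats::lm(stats::as.formula(paste(".y ~", paste(covariates, collapse = " + "))),
                     data = d[cc, ])
    r[cc] <- stats::residuals(fit)
    r
  } else {
    y - mean(y)
  }
  series <- purrr::imap(split(seq_along(y), cl), function(ix, lev) {
    if (length(ix) < min_points) return(NULL)
    tt <- tnum[ix]; rr <- resid[ix]
    ok <- !is.na(rr)
    if (sum(ok) < min_points) return(NULL)
    df <- data.frame(t = tt[ok], r = rr[ok])
    if (length(unique(df$t)) < 4) return(NULL)
    lo <- stats::loess(r ~ t, data = df, span = span, degree = degree)
    grid <- seq(min(df$t), max(df$t), length.out = grid_n)
    tibble::tibble(class = lev, time = grid,
                   smoothed = stats::predict(lo, newdata = data.frame(t = grid)))
  })
  series <- dplyr::bind_rows(purrr::compact(series))
  dq_result_row(NA_character_, response, 0L, length(y),
                grading = if (nrow(series) == 0) "not-applicable" else "ok",
                descriptor = list(series = series, span = span, degree = degree,
                                  class_var = class_var),
                subclass = "dq_loess")
}
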