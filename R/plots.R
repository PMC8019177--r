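# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for data quality results
#'
#' `autoplot()` methods mirror the panels of a typical assessment report:
#' an applicability heatmap, histograms with limit lines, per-reason
#' missingness bars, margins plots with class-wise confidence intervals,
#' and LOESS trend curves.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name dq-plots
NULL

#' @rdname dq-plots
#' @exportS3Method ggplot2::autoplot
autoplot.dq_applicability <- function(object, ...) {
  ggplot2::ggplot(object$matrix,
                  ggplot2::aes(x = .data$check, y = .data$variable,
                               fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(
      applicable = "#2e7d32", `no-metadata` = "#9e9e9e",
      `no-data` = "#eceff1", `type-mismatch` = "#c62828")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "status",
                  title = "Applicability of checks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname dq-plots
#' @exportS3Method ggplot2::autoplot
autoplot.dq_limit_deviations <- function(object, ...) {
  d <- object$descriptor[[1]]
  if (is.null(d$breaks)) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "No histogram available"))
  }
  df <- tibble::tibble(mid = (d$breaks[-1] + d$breaks[-length(d$breaks)]) / 2,
                       count = d$counts,
                       width = diff(d$breaks))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = df$width, fill = "steelblue", color = "white") +
    ggplot2::labs(x = object$variable[1], y = "count",
                  title = paste("Limit deviations:", object$variable[1])) +
    ggplot2::theme_minimal()
  if (!is.null(d$hard)) p <- p + ggplot2::geom_vline(xintercept = d$hard,
                                                     color = "red", linetype = 1)
  if (!is.null(d$soft)) p <- p + ggplot2::geom_vline(xintercept = d$soft,
                                                     color = "orange", linetype = 2)
  p
}

#' @rdname dq-plots
#' @exportS3Method ggplot2::autoplot
autoplot.dq_margins <- function(object, ...) {
  d <- object$descriptor[[1]]
  pc <- d$per_class
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$class, y = .data$estimate,
                                   color = .data$flagged)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::geom_hline(yintercept = d$overall, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "#c62828")) +
    ggplot2::labs(x = d$class_var, y = paste("adjusted mean of", object$variable[1]),
                  title = "Covariate-adjusted marginal means by class") +
    ggplot2::theme_minimal()
}

#' @rdname dq-plots
#' @exportS3Method ggplot2::autoplot
autoplot.dq_loess <- function(object, ...) {
  s <- object$descriptor[[1]]$series
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$smoothed,
                                  color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "smoothed residual",
                  title = paste("LOESS trend:", object$variable[1])) +
    ggplot2::theme_minimal()
}

#' Plot item missingness per reason
#'
#' Stacked bar per variable: observed, system missing, each missing and
#' jump code.
#'
#' @param x A [item_missingness()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_item_missingness <- function(x, ...) {
  b <- x$breakdown
  long <- purrr::pmap_dfr(b, function(variable, n_expected, n_observed,
                                      n_system_missing, per_code, per_jump) {
    tibble::tibble(
      variable = variable,
      reason = c("observed", "system missing",
                 paste0("code ", names(per_code)), paste0("jump ", names(per_jump))),
      n = c(n_observed, n_system_missing,
            unlist(per_code, use.names = FALSE) %||% integer(),
            unlist(per_jump, use.names = FALSE) %||% integer()))
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$n,
                                     fill = .data$reason)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "data fields", fill = "status",
                  title = "Item missingness by reason") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
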