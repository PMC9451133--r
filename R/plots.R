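#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_tile geom_text labs theme_minimal scale_fill_manual coord_flip
NULL

#' QQ plot of observed versus expected p-values
#'
#' Observed -log10(p) (computed on the mantissa/exponent representation, so
#' extreme associations plot correctly) against the uniform expectation. A
#' calibrated null study tracks the identity line; an excess above it at the
#' tail reflects true associations or confounding.
#'
#' @param object a [sumstats] dataset.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sumstats <- function(object, ...) {
  lp <- -pval_log10(object$p_value)
  lp <- sort(lp[!is.na(lp)], decreasing = TRUE)
  n <- length(lp)
  df <- tibble(
    expected = -log10(stats::ppoints(n)),
    observed = lp
  )
  ggplot(df, aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = expression(Expected ~ -log[10](p)),
         y = expression(Observed ~ -log[10](p)),
         title = "P-value QQ plot") +
    theme_minimal()
}

#' Plot validation findings by code
#'
#' @param object a `sumstats_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sumstats_report <- function(object, ...) {
  counts <- tibble(
    code = names(object$counts_by_code),
    n = as.integer(object$counts_by_code)
  )
  counts$severity <- issue_severity(counts$code)
  ggplot(counts, aes(x = stats::reorder(.data$code, .data$n), y = .data$n,
                     fill = .data$severity)) +
    geom_col() +
    coord_flip() +
    scale_fill_manual(values = c(ERROR = "#b2182b", WARNING = "#ef8a62")) +
    labs(x = NULL, y = "findings",
         title = sprintf("Validation findings (%s)",
                         if (object$valid) "valid" else "invalid")) +
    theme_minimal()
}

#' Plot a FAIR assessment as an indicator board
#'
#' @param object a `fair_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fair_report <- function(object, ...) {
  df <- tidy.fair_report(object)
  df$indicator <- factor(df$indicator, levels = rev(df$indicator))
  ggplot(df, aes(x = 1, y = .data$indicator, fill = .data$status)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$status), size = 3) +
    scale_fill_manual(values = c(pass = "#66bd63", fail = "#d73027",
                                 not_auto_checkable = "grey80")) +
    labs(x = NULL, y = NULL, title = "FAIR indicators") +
    theme_minimal()
}
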