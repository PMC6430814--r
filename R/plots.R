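#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs theme_bw scale_colour_manual geom_hline facet_wrap
#' @export
ggplot2::autoplot

#' Plot the crosslink sequence propensity
#'
#' Relative frequency of each nucleotide by offset from the crosslink site,
#' the diagnostic that makes the uridine enrichment at the truncation point
#' visible. T is rendered as U (the counts come from RNA).
#'
#' @param object A `bias_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bias_table <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(unclass(object), stringsAsFactors = FALSE))
  names(df) <- c("base", "offset", "q")
  df$offset <- as.integer(df$offset)
  df$base <- ifelse(df$base == "T", "U", df$base)
  ggplot(df, aes(x = .data$offset, y = 100 * .data$q, colour = .data$base)) +
    geom_line() +
    geom_hline(yintercept = 25, linetype = "dashed", colour = "grey50") +
    labs(x = "offset from crosslink site (nt)", y = "relative frequency (%)",
         colour = NULL) +
    theme_bw()
}

#' Plot the fitted mean-CV2 variance trend
#'
#' @param object A `variance_trend`.
#' @param ... Unused.
#' @return A ggplot of moderated CV2 against log2 mean normalised count.
#' @export
autoplot.variance_trend <- function(object, ...) {
  grid <- tidy(object)
  ggplot(grid, aes(x = .data$log2_mu, y = .data$cv2)) +
    geom_line(colour = "firebrick") +
    labs(x = expression(log[2] ~ "mean normalised count"),
         y = expression(CV^2)) +
    theme_bw()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot; the AUC is shown in the subtitle.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$recall, y = .data$precision)) +
    geom_line() +
    labs(x = "recall", y = "precision",
         subtitle = sprintf("PR-AUC = %.3f", attr(object, "auc"))) +
    theme_bw()
}

#' Plot the percentage of ASB calls per coverage bin
#'
#' Overdispersion diagnostic: methods that underestimate count variance
#' call ever more events as coverage grows, while a well-calibrated test
#' stays near the true ASB fraction.
#'
#' @param data Tibble from [percent_asb_by_coverage()], optionally with a
#'   `method` column for faceting.
#' @param true_pct Horizontal reference line (default 10, the simulated ASB
#'   percentage); `NULL` for none.
#' @return A ggplot.
#' @export
plot_percent_asb <- function(data, true_pct = 10) {
  p <- ggplot(data, aes(x = .data$bin, y = .data$pct_asb)) +
    geom_col(fill = "steelblue") +
    labs(x = "mean read coverage", y = "% ASB among testable SNVs") +
    theme_bw()
  if ("method" %in% names(data)) p <- p + facet_wrap(~method)
  if (!is.null(true_pct)) {
    p <- p + geom_hline(yintercept = true_pct, linetype = "dashed",
                        colour = "firebrick")
  }
  p
}
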