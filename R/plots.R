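#' Forest plot of MR results
#'
#' One row per (outcome, exposure label, method), point estimate with 95%
#' CI. For binary outcomes pass `odds_ratio = TRUE` to exponentiate onto
#' the OR scale with a reference line at 1.
#'
#' @param results data.frame from [run_mr()] or [mr_all()] (needs
#'   `estimate`, `ci_low`, `ci_high` and label columns).
#' @param odds_ratio Plot `exp(estimate)` on a log-scaled axis.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, odds_ratio = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_forest needs the ggplot2 package", call. = FALSE)
  }
  d <- as.data.frame(results)
  if (is.null(d$exposure_label)) d$exposure_label <- d$method
  if (is.null(d$outcome)) d$outcome <- ""
  d$label <- paste(d$outcome, d$exposure_label, d$method, sep = " | ")
  ref <- 0
  if (odds_ratio) {
    d$estimate <- exp(d$estimate); d$ci_low <- exp(d$ci_low); d$ci_high <- exp(d$ci_high)
    ref <- 1
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (odds_ratio) "Odds ratio (95% CI)" else "Estimate (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (odds_ratio) p <- p + ggplot2::scale_x_log10()
  p
}

#' Heatmap of rejection rates from a power grid
#'
#' One panel per true effect size, outcome sample size against variance
#' explained, filled by the rejection rate of the selected tissue.
#'
#' @param power A `power_table` from [power_grid()].
#' @param tissue Tissue to display.
#' @return A ggplot object.
#' @export
plot_power_heatmap <- function(power, tissue = "adipose") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_power_heatmap needs the ggplot2 package", call. = FALSE)
  }
  d <- power[power$tissue == tissue, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_outcome),
                                  y = factor(.data$varexp),
                                  fill = .data$rejection_rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rejection_rate)),
                       size = 3) +
    ggplot2::facet_wrap(~effect, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    ggplot2::labs(x = "Outcome sample size", y = "Variance explained per tissue",
                  fill = "Power") +
    ggplot2::theme_minimal()
}
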