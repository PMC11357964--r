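#' Training-history plot
#'
#' Global error (summed per-bag squared error) per epoch, with the
#' Hosmer-Lemeshow p-value traced on a second panel when available.
#'
#' @param object A `mil_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mil_fit
#' @export
autoplot.mil_fit <- function(object, ...) {
  hist <- object$history |>
    tidyr::pivot_longer(c("global_err", "hl_p"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      global_err = "Global error",
      hl_p = "HL p-value"
    ))
  ggplot2::ggplot(hist, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "Epoch", y = NULL,
      title = sprintf("Training history (%s loss)", object$loss)
    ) +
    ggplot2::theme_minimal()
}

#' Calibration plot for an HL table
#'
#' Observed versus expected effectiveness mass per calibration group; a
#' well-calibrated model hugs the identity line.
#'
#' @param object An `hl_table` from [bin_bags()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hl_table
#' @export
autoplot.hl_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$expected_A / .data$n, .data$observed_A / .data$n)
  ) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Mean predicted effectiveness",
      y = "Mean observed effectiveness",
      title = "Calibration by risk group"
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of the stratified cohort
#'
#' Step survival curves for the high- and low-risk strata.
#'
#' @param object A `stratification_report` with KM curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stratification_report
#' @export
autoplot.stratification_report <- function(object, ...) {
  if (is.null(object$km_curves)) {
    stop("No Kaplan-Meier curves in this report.", call. = FALSE)
  }
  anchor <- object$km_curves |>
    dplyr::group_by(.data$group) |>
    dplyr::slice(1) |>
    dplyr::mutate(time = 0, survival = 1) |>
    dplyr::ungroup()
  curves <- dplyr::bind_rows(anchor, object$km_curves)
  ggplot2::ggplot(
    curves,
    ggplot2::aes(.data$time, .data$survival, colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(
      values = c(high = "#d7301f", low = "#2c7fb8"),
      labels = c(high = "High risk", low = "Low risk")
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Survival probability", colour = NULL,
      title = sprintf(
        "Survival by risk stratum (log-rank p = %.2g)",
        object$logrank_pvalue
      )
    ) +
    ggplot2::theme_minimal()
}

#' Risk distribution by stratum
#'
#' Box/jitter plot of predicted failure risks in the high- and low-risk
#' groups, annotated with the Welch t-test p-value.
#'
#' @param report A `stratification_report`.
#' @return A ggplot object.
#' @export
plot_risk_distribution <- function(report) {
  stopifnot(inherits(report, "stratification_report"))
  ggplot2::ggplot(
    report$data,
    ggplot2::aes(.data$group, .data$risk, colour = .data$group)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(high = "#d7301f", low = "#2c7fb8"), guide = "none"
    ) +
    ggplot2::labs(
      x = NULL, y = "Predicted failure risk",
      title = sprintf(
        "Failure risk by stratum (Welch t-test p = %.2g)",
        report$t_pvalue
      )
    ) +
    ggplot2::theme_minimal()
}
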