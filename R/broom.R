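#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted multi-instance network
#'
#' @param x A `mil_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `global_err`,
#'   `hl_statistic`, `hl_df`, `hl_p`.
#' @method tidy mil_fit
#' @export
tidy.mil_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted multi-instance network
#'
#' @param x A `mil_fit`.
#' @param ... Unused.
#' @return Tibble with `loss`, `epochs_run`, `converged`, the final
#'   `global_err`, `hl_statistic` and `hl_p`.
#' @method glance mil_fit
#' @export
glance.mil_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    loss = x$loss,
    epochs_run = x$epochs_run,
    converged = x$converged,
    global_err = last$global_err,
    hl_statistic = last$hl_statistic,
    hl_p = last$hl_p
  )
}

#' Tidy a Hosmer-Lemeshow result
#'
#' @param x An `hl_result`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `Q`.
#' @method tidy hl_result
#' @export
tidy.hl_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value, Q = x$Q
  )
}

#' Tidy an optimal-threshold result
#'
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return One-row tibble with `tau`, `diff`, `split_index`,
#'   `candidates_considered`, `margin`, `degenerate`.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble::tibble(
    tau = x$tau, diff = x$diff, split_index = x$split_index,
    candidates_considered = x$candidates_considered,
    margin = x$margin, degenerate = x$degenerate
  )
}

#' Tidy a stratification report (per-group summary)
#'
#' @param x A `stratification_report`.
#' @param ... Unused.
#' @return The per-group summary tibble (group, n, mean_risk,
#'   mean_survival).
#' @method tidy stratification_report
#' @export
tidy.stratification_report <- function(x, ...) {
  x$groups
}

#' One-row summary of a stratification report
#'
#' @param x A `stratification_report`.
#' @param ... Unused.
#' @return Tibble with `tau`, group sizes and mean risks, `t_statistic`,
#'   `t_pvalue`, `logrank_statistic`, `logrank_pvalue`.
#' @method glance stratification_report
#' @export
glance.stratification_report <- function(x, ...) {
  g <- x$groups
  get1 <- function(col, grp) {
    v <- g[[col]][g$group == grp]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    tau = x$tau,
    n_high = get1("n", "high"),
    n_low = get1("n", "low"),
    mean_risk_high = get1("mean_risk", "high"),
    mean_risk_low = get1("mean_risk", "low"),
    mean_survival_high = get1("mean_survival", "high"),
    mean_survival_low = get1("mean_survival", "low"),
    t_statistic = x$t_statistic,
    t_pvalue = x$t_pvalue,
    logrank_statistic = x$logrank_statistic,
    logrank_pvalue = x$logrank_pvalue
  )
}
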