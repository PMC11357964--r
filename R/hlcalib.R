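#' Group bag predictions into Hosmer-Lemeshow calibration bins
#'
#' Sorts bags by predicted value (ties kept in input order), splits them into
#' `Q` contiguous groups of near-equal size (any remainder spread over the
#' first groups — decile-of-risk binning), and accumulates per group the
#' observed and expected mass of the event "drug effective": `expected_A` is
#' the sum of predictions in the group, `observed_A` the sum of labels, and
#' the `not_A` columns the complements `1 - value` summed the same way. With
#' 0/1 labels this reproduces the classical Hosmer-Lemeshow table; with
#' continuous labels in \[0, 1\] it is the natural extension in which each
#' bag contributes its label mass.
#'
#' @param predictions Numeric vector of predicted values in \[0, 1\].
#' @param labels Numeric vector of observed values in \[0, 1\], same length.
#' @param Q Number of calibration groups (default 10).
#' @return An `hl_table`: tibble with columns `group`, `n`, `observed_A`,
#'   `expected_A`, `observed_not_A`, `expected_not_A`.
#' @export
bin_bags <- function(predictions, labels, Q = 10) {
  n <- length(predictions)
  if (length(labels) != n) {
    stop("`predictions` and `labels` must have equal length.", call. = FALSE)
  }
  if (Q < 1 || n < Q) {
    stop("Need at least Q = ", Q, " observations; got ", n, ".", call. = FALSE)
  }
  if (any(predictions < 0 | predictions > 1) || any(labels < 0 | labels > 1)) {
    stop("Predictions and labels must lie in [0, 1].", call. = FALSE)
  }
  ord <- order(predictions) # ties keep input order (stable sort)
  base <- n %/% Q
  extra <- n %% Q
  sizes <- rep(base, Q) + c(rep(1L, extra), rep(0L, Q - extra))
  grp <- rep(seq_len(Q), times = sizes)
  p <- predictions[ord]
  y <- labels[ord]
  out <- tibble::tibble(group = grp, p = p, y = y) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      observed_A = sum(.data$y),
      expected_A = sum(.data$p),
      observed_not_A = sum(1 - .data$y),
      expected_not_A = sum(1 - .data$p),
      .groups = "drop"
    )
  structure(out, class = c("hl_table", class(out)))
}

#' Hosmer-Lemeshow statistic from a calibration table
#'
#' Computes `sum_q (obsA - expA)^2 / expA + (obsNotA - expNotA)^2 / expNotA`.
#' Groups whose expected mass is zero on either side are merged with the
#' following group (the last group merges backwards) before the statistic is
#' evaluated; the post-merge number of groups is returned as an attribute so
#' the degrees of freedom track the merge.
#'
#' @param table An `hl_table` from [bin_bags()], or any data frame with the
#'   four observed/expected columns.
#' @return The nonnegative statistic, with attribute `Q` (post-merge group
#'   count).
#' @export
hl_statistic <- function(table) {
  need <- c("observed_A", "expected_A", "observed_not_A", "expected_not_A")
  stopifnot(all(need %in% names(table)))
  tab <- as.data.frame(table)[, need]
  tab <- merge_zero_expected(tab)
  if (any(tab$expected_A <= 0) || any(tab$expected_not_A <= 0)) {
    stop("Every group must have positive expected mass on both sides; ",
      "merge groups or fall back to a squared-error term.",
      call. = FALSE
    )
  }
  stat <- sum(
    (tab$observed_A - tab$expected_A)^2 / tab$expected_A +
      (tab$observed_not_A - tab$expected_not_A)^2 / tab$expected_not_A
  )
  attr(stat, "Q") <- nrow(tab)
  stat
}

merge_zero_expected <- function(tab) {
  repeat {
    bad <- which(tab$expected_A == 0 | tab$expected_not_A == 0)
    if (length(bad) == 0L || nrow(tab) == 1L) {
      return(tab)
    }
    i <- bad[1]
    j <- if (i == nrow(tab)) i - 1L else i + 1L
    tab[j, ] <- tab[i, ] + tab[j, ]
    tab <- tab[-i, , drop = FALSE]
  }
}

#' Upper-tail p-value for the Hosmer-Lemeshow statistic
#'
#' The statistic is referred to a chi-square distribution with `Q - 2`
#' degrees of freedom; the p-value is the upper-tail probability
#' `P(chisq_{Q-2} > statistic)`.
#'
#' @param statistic Nonnegative HL statistic.
#' @param Q Number of calibration groups (must be at least 3 so that the
#'   degrees of freedom are positive).
#' @return p-value in \[0, 1\].
#' @export
hl_pvalue <- function(statistic, Q) {
  if (Q < 3) {
    stop("Q must be >= 3 (degrees of freedom Q - 2 must be positive).",
      call. = FALSE
    )
  }
  if (statistic < 0) stop("The HL statistic is nonnegative.", call. = FALSE)
  stats::pchisq(statistic, df = Q - 2, lower.tail = FALSE)
}

#' Hosmer-Lemeshow calibration test
#'
#' Convenience wrapper: bins predictions and labels with [bin_bags()],
#' evaluates the statistic and refers it to chi-square with `Q - 2` degrees
#' of freedom (post-merge `Q` if empty groups were merged).
#'
#' @inheritParams bin_bags
#' @return An `hl_result`: list with `statistic`, `df`, `p_value`, `Q`.
#' @examples
#' p <- runif(200)
#' y <- rbinom(200, 1, p)
#' hl_test(p, y)
#' @export
hl_test <- function(predictions, labels, Q = 10) {
  tab <- bin_bags(predictions, labels, Q)
  stat <- hl_statistic(tab)
  q_eff <- attr(stat, "Q")
  structure(
    list(
      statistic = as.numeric(stat),
      df = q_eff - 2L,
      p_value = hl_pvalue(as.numeric(stat), q_eff),
      Q = q_eff
    ),
    class = "hl_result"
  )
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow test: statistic = %.4f, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p_value
  ))
  invisible(x)
}
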