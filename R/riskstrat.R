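#' Optimal positive threshold on mutation abundance
#'
#' Sorts patients by mutation abundance and scans the candidate split points
#' whose abundance lies within `margin` of the mean abundance. At split `t`
#' the objective is the absolute difference between the mean predicted
#' failure risk of the upper group (above the split) and the lower group;
#' the split maximising this difference defines the threshold, taken as the
#' midpoint between the two abundances flanking the optimal split so no
#' training patient sits exactly on the boundary. Ties go to the smallest
#' split index.
#'
#' @param abundances Numeric mutation-abundance values, one per patient.
#' @param risks Predicted failure risks in \[0, 1\], aligned with
#'   `abundances`.
#' @param margin Half-width of the search window around `mean(abundances)`;
#'   `Inf` admits every split. Defaults to a quarter of the abundance range.
#' @return A `threshold_result`: list with `tau`, `diff`, `split_index`,
#'   `candidates_considered`, `margin`, and `degenerate` (TRUE when every
#'   candidate split gives the same objective value).
#' @export
optimal_threshold <- function(abundances, risks,
                              margin = 0.25 * diff(range(abundances))) {
  n <- length(abundances)
  if (length(risks) != n) {
    stop("`abundances` and `risks` must have equal length.", call. = FALSE)
  }
  if (n < 2) stop("Need at least two patients.", call. = FALSE)
  if (any(risks < 0 | risks > 1)) {
    stop("Risks must lie in [0, 1].", call. = FALSE)
  }
  if (margin < 0) stop("`margin` must be nonnegative.", call. = FALSE)

  ord <- order(abundances)
  a <- abundances[ord]
  d <- risks[ord]
  center <- mean(abundances)
  splits <- seq_len(n - 1L)
  in_window <- a[splits] >= center - margin & a[splits] <= center + margin
  candidates <- splits[in_window]
  if (length(candidates) == 0L) {
    stop("No candidate split falls inside the search window; ",
      "increase `margin`.",
      call. = FALSE
    )
  }
  # exhaustive evaluation with plain group means, so tie-breaking is exact
  objective <- vapply(candidates, function(t) {
    abs(mean(d[(t + 1):n]) - mean(d[1:t]))
  }, numeric(1))
  best <- candidates[which.max(objective)] # which.max takes the first tie
  structure(
    list(
      tau = (a[best] + a[best + 1L]) / 2,
      diff = max(objective),
      split_index = best,
      candidates_considered = length(candidates),
      margin = margin,
      degenerate = length(unique(round(objective, 15))) == 1L &&
        length(candidates) > 1L
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Optimal positive threshold tau = %.4f (risk difference %.4f, split %d of %d candidates)\n",
    x$tau, x$diff, x$split_index, x$candidates_considered
  ))
  if (x$degenerate) cat("  (degenerate: all splits tie)\n")
  invisible(x)
}

#' Stratify patients into high- and low-risk groups at a threshold
#'
#' Patients with mutation abundance strictly below `tau` form the high-risk
#' group; abundance at or above `tau` is low-risk. Group mean risks are
#' reported, and when both groups are populated and non-degenerate the
#' between-group Welch t-test on risks and the Kaplan-Meier/log-rank
#' comparison of survival are run.
#'
#' @param patients Patient tibble with `mutation_abundance`,
#'   `survival_months` and (optionally) `event` columns.
#' @param risks Predicted failure risks aligned with `patients`.
#' @param tau Abundance threshold.
#' @return A `stratification_report`: list with `tau`, a `groups` summary
#'   tibble (group, n, mean_risk, mean_survival), `t_statistic`,
#'   `t_pvalue`, `logrank_statistic`, `logrank_pvalue`, `km_curves`
#'   (tibble: group, time, survival, n_risk), and per-patient `data`.
#' @export
stratify <- function(patients, risks, tau) {
  stopifnot(is.data.frame(patients), "mutation_abundance" %in% names(patients))
  if (!is.finite(tau)) stop("`tau` must be finite.", call. = FALSE)
  if (length(risks) != nrow(patients)) {
    stop("`risks` must align with `patients`.", call. = FALSE)
  }
  event <- if ("event" %in% names(patients)) patients$event else
    rep(1L, nrow(patients))
  dat <- tibble::tibble(
    mutation_abundance = patients$mutation_abundance,
    survival_months = patients$survival_months,
    event = as.integer(event),
    risk = risks,
    group = ifelse(patients$mutation_abundance < tau, "high", "low")
  )
  groups <- dat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_risk = mean(.data$risk),
      mean_survival = mean(.data$survival_months),
      .groups = "drop"
    )
  report <- list(
    tau = tau, groups = groups, data = dat,
    t_statistic = NA_real_, t_pvalue = NA_real_,
    logrank_statistic = NA_real_, logrank_pvalue = NA_real_,
    km_curves = NULL
  )
  class(report) <- "stratification_report"
  if (length(unique(dat$group)) < 2L) {
    warning("One stratum is empty at tau = ", signif(tau, 4),
      "; group comparisons skipped.",
      call. = FALSE
    )
    return(report)
  }
  tt <- tryCatch(
    risk_t_test(dat$risk[dat$group == "high"], dat$risk[dat$group == "low"]),
    error = function(e) {
      warning("Risk t-test skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    }
  )
  if (!is.null(tt)) {
    report$t_statistic <- tt$statistic
    report$t_pvalue <- tt$p_value
  }
  km <- tryCatch(
    km_logrank(dat$survival_months, dat$event, dat$group),
    warning = function(w) {
      warning(w)
      NULL
    },
    error = function(e) {
      warning("Survival comparison skipped: ", conditionMessage(e),
        call. = FALSE
      )
      NULL
    }
  )
  if (!is.null(km)) {
    report$km_curves <- km$km_curves
    report$logrank_statistic <- km$logrank_statistic
    report$logrank_pvalue <- km$logrank_pvalue
  }
  report
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("Risk stratification at tau = %.4f\n", x$tau))
  print(x$groups)
  cat(sprintf(
    "Welch t-test: t = %.3f, p = %.3g; log-rank: chisq = %.3f, p = %.3g\n",
    x$t_statistic, x$t_pvalue, x$logrank_statistic, x$logrank_pvalue
  ))
  invisible(x)
}

#' Welch two-sample t-test on group risks
#'
#' Two-sided independent-samples t-test (unequal variances) comparing the
#' predicted failure risks of the high- and low-risk groups.
#'
#' @param risks_high,risks_low Numeric risk vectors, each with at least two
#'   values and nonzero pooled variance.
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
risk_t_test <- function(risks_high, risks_low) {
  if (length(risks_high) < 2L || length(risks_low) < 2L) {
    stop("Each group needs at least two observations.", call. = FALSE)
  }
  if (stats::var(risks_high) == 0 && stats::var(risks_low) == 0) {
    if (mean(risks_high) == mean(risks_low)) {
      return(list(t_statistic = 0, p_value = 1, df = NA_real_))
    }
    stop("Both groups are constant; the t-test variance is degenerate.",
      call. = FALSE
    )
  }
  tt <- stats::t.test(risks_high, risks_low, var.equal = FALSE)
  list(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter)
  )
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the two-group log-rank
#' chi-square (1 degree of freedom) with its upper-tail p-value.
#'
#' @param times Survival times in months.
#' @param events Event indicators (1 = event observed, 0 = censored).
#' @param group_labels Group membership (exactly two distinct values).
#' @return List with `km_curves` (tibble: group, time, survival, n_risk),
#'   `logrank_statistic`, `logrank_pvalue`.
#' @export
km_logrank <- function(times, events, group_labels) {
  group_labels <- as.character(group_labels)
  if (length(unique(group_labels)) != 2L) {
    stop("Exactly two groups are required.", call. = FALSE)
  }
  events <- as.integer(events)
  fit <- survival::survfit(
    survival::Surv(times, events) ~ group_labels
  )
  strata_names <- sub("^group_labels=", "", names(fit$strata))
  curves <- tibble::tibble(
    group = rep(strata_names, fit$strata),
    time = fit$time,
    survival = fit$surv,
    n_risk = fit$n.risk
  )
  per_group_events <- tapply(events, group_labels, sum)
  if (any(per_group_events == 0)) {
    warning("A group has no observed events; log-rank test skipped.",
      call. = FALSE
    )
    return(list(
      km_curves = curves,
      logrank_statistic = NA_real_,
      logrank_pvalue = NA_real_
    ))
  }
  lr <- survival::survdiff(survival::Surv(times, events) ~ group_labels)
  list(
    km_curves = curves,
    logrank_statistic = unname(lr$chisq),
    logrank_pvalue = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  )
}
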