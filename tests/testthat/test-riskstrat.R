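test_that("the threshold search solves the worked example exactly", {
  res <- optimal_threshold(
    abundances = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8),
    risks = c(0.9, 0.8, 0.85, 0.3, 0.2, 0.25),
    margin = Inf
  )
  expect_equal(res$split_index, 3)
  expect_equal(res$diff, 0.6)
  expect_equal(res$tau, 0.45)
  expect_equal(res$candidates_considered, 5)
  expect_false(res$degenerate)
})

test_that("the threshold search equals brute force over all splits", {
  brute <- function(a, d) {
    ord <- order(a)
    a <- a[ord]; d <- d[ord]
    n <- length(a)
    best_t <- NA; best_diff <- -Inf
    for (t in 1:(n - 1)) {
      dd <- abs(mean(d[(t + 1):n]) - mean(d[1:t]))
      if (dd > best_diff + 1e-15) {
        best_diff <- dd; best_t <- t
      }
    }
    list(t = best_t, diff = best_diff, tau = (a[best_t] + a[best_t + 1]) / 2)
  }
  withr::with_seed(200, {
    for (i in 1:100) {
      n <- sample(2:500, 1)
      a <- runif(n)
      d <- runif(n)
      res <- optimal_threshold(a, d, margin = Inf)
      ref <- brute(a, d)
      expect_identical(res$split_index, ref$t)
      expect_equal(res$diff, ref$diff, tolerance = 1e-12)
      expect_equal(res$tau, ref$tau, tolerance = 1e-12)
    }
  })
})

test_that("degenerate and windowed searches behave as documented", {
  # constant risks: every split ties at zero, smallest split wins
  res <- optimal_threshold(c(0.1, 0.4, 0.9), rep(0.5, 3), margin = Inf)
  expect_equal(res$split_index, 1)
  expect_equal(res$diff, 0)
  expect_true(res$degenerate)
  # window excludes every split
  expect_error(
    optimal_threshold(c(0.01, 0.99), c(0.2, 0.8), margin = 0.05),
    "margin"
  )
  # window restricts candidates around the abundance mean
  a <- c(0.05, 0.45, 0.5, 0.55, 0.95)
  res2 <- optimal_threshold(a, c(1, 0.9, 0.5, 0.1, 0), margin = 0.2)
  expect_equal(res2$candidates_considered, 3)
  expect_error(optimal_threshold(0.4, 0.5), "two patients")
})

test_that("stratification assigns abundance below tau to high risk", {
  patients <- tibble::tibble(
    mutation_abundance = c(0.3, 0.6),
    survival_months = c(9, 17),
    event = c(1, 1)
  )
  rep1 <- suppressWarnings(stratify(patients, c(0.8, 0.2), tau = 0.45))
  expect_equal(sort(rep1$groups$n), c(1, 1))
  expect_equal(rep1$groups$mean_risk[rep1$groups$group == "high"], 0.8)
  # the boundary itself is low risk (>= tau)
  rep2 <- suppressWarnings(
    stratify(dplyr::mutate(patients, mutation_abundance = c(0.45, 0.6)),
      c(0.8, 0.2),
      tau = 0.45
    )
  )
  expect_warning(
    stratify(patients, c(0.8, 0.2), tau = 0.1),
    "stratum is empty"
  )
  expect_equal(nrow(rep2$groups), 1) # everyone low risk
})

test_that("group risk means recompute exactly as arithmetic means", {
  withr::with_seed(210, {
    patients <- simulate_cohort(60, seed = 211)
    risks <- runif(60)
    rep <- stratify(patients, risks, tau = 0.5)
    high <- patients$mutation_abundance < 0.5
    expect_equal(
      rep$groups$mean_risk[rep$groups$group == "high"], mean(risks[high])
    )
    expect_equal(
      rep$groups$mean_risk[rep$groups$group == "low"], mean(risks[!high])
    )
    expect_equal(sum(rep$groups$n), 60)
  })
})

test_that("the Welch t-test matches the textbook formula", {
  # identical groups: no difference
  same <- c(0.2, 0.4, 0.6)
  res <- risk_t_test(same, same)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  withr::with_seed(220, {
    for (i in 1:50) {
      a <- runif(sample(3:30, 1))
      b <- runif(sample(3:30, 1))
      res <- risk_t_test(a, b)
      # textbook Welch statistic and Satterthwaite df
      se2 <- var(a) / length(a) + var(b) / length(b)
      t_ref <- (mean(a) - mean(b)) / sqrt(se2)
      df_ref <- se2^2 / (
        (var(a) / length(a))^2 / (length(a) - 1) +
          (var(b) / length(b))^2 / (length(b) - 1)
      )
      p_ref <- 2 * stats::pt(-abs(t_ref), df_ref)
      expect_equal(res$t_statistic, t_ref, tolerance = 1e-10)
      expect_equal(res$df, df_ref, tolerance = 1e-10)
      expect_equal(res$p_value, p_ref, tolerance = 1e-10)
      # swapping the groups flips the sign but not the p-value
      flipped <- risk_t_test(b, a)
      expect_equal(flipped$t_statistic, -t_ref, tolerance = 1e-10)
      expect_equal(flipped$p_value, p_ref, tolerance = 1e-10)
    }
  })
  expect_error(risk_t_test(0.5, c(0.1, 0.2)), "at least two")
})

test_that("Kaplan-Meier without censoring is the empirical survival curve", {
  times <- c(2, 4, 6, 8, 10, 12)
  groups <- rep(c("high", "low"), each = 3)
  res <- km_logrank(times, rep(1, 6), groups)
  high_curve <- dplyr::filter(res$km_curves, group == "high")
  expect_equal(high_curve$time, c(2, 4, 6))
  expect_equal(high_curve$survival, c(2 / 3, 1 / 3, 0))
  # identical event times in both groups: no separation
  res2 <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6), groups)
  expect_equal(res2$logrank_statistic, 0, tolerance = 1e-12)
  expect_equal(res2$logrank_pvalue, 1, tolerance = 1e-12)
})

test_that("the log-rank statistic matches a hand-computed 6-patient table", {
  # groups A = {1, 3, 5}, B = {2, 4, 6}, all events observed.
  # Observed events in A: 3. Expected under the null, summing over event
  # times t with nA(t)/n(t): 3/6 + 2/5 + 2/4 + 1/3 + 1/2 + 0 = 2.2333...
  # Variance sum: V = sum nA*nB*(n-d)/(n^2*(n-1)) with d = 1 each time.
  times <- 1:6
  groups <- rep(c("A", "B"), 3)
  nA <- c(3, 2, 2, 1, 1, 0)
  ntot <- 6:1
  expected_A <- sum(nA / ntot)
  v <- sum(nA / ntot * (1 - nA / ntot) * 1)
  chisq_ref <- (3 - expected_A)^2 / v
  res <- km_logrank(times, rep(1, 6), groups)
  expect_equal(res$logrank_statistic, chisq_ref, tolerance = 1e-10)
  expect_equal(res$logrank_pvalue,
    stats::pchisq(chisq_ref, 1, lower.tail = FALSE),
    tolerance = 1e-12
  )
})

test_that("a group without events skips the log-rank test with a warning", {
  expect_warning(
    res <- km_logrank(c(3, 5, 7, 9), c(1, 1, 0, 0), c("a", "a", "b", "b")),
    "no observed events"
  )
  expect_true(is.na(res$logrank_statistic))
  expect_s3_class(res$km_curves, "tbl_df")
})

test_that("threshold recovery works end-to-end on simulated cohorts", {
  cohort <- simulate_cohort(400, seed = 300, true_threshold = 0.5,
    benefit_months = 8
  )
  inc <- filter_cohort(cohort, 8)
  lab <- fit_effectiveness_labels(inc$survival_months)
  risks <- failure_risk(lab$labels)
  res <- optimal_threshold(inc$mutation_abundance, risks)
  expect_lt(abs(res$tau - 0.5), 0.05)
  rep <- stratify(inc, risks, res$tau)
  g <- rep$groups
  expect_gt(
    g$mean_risk[g$group == "high"], g$mean_risk[g$group == "low"]
  )
  expect_lt(
    g$mean_survival[g$group == "high"], g$mean_survival[g$group == "low"]
  )
  # monotone response: deepening the risk contrast increases the objective
  risks2 <- ifelse(inc$mutation_abundance >= 0.5,
    pmax(0, risks - 0.1), risks
  )
  res2 <- optimal_threshold(inc$mutation_abundance, risks2)
  expect_gt(res2$diff, res$diff)
})
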