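#' Filter a cohort to patients whose survival exceeds a floor
#'
#' Keeps patients whose `survival_months` is strictly greater than
#' `min_months` (8 months by default), the inclusion rule applied before
#' effectiveness labels are fitted. Row order is preserved.
#'
#' @param patients Patient tibble with a `survival_months` column.
#' @param min_months Inclusion floor in months; strictly-greater comparison.
#' @return The filtered tibble. Warns if no patient survives the filter.
#' @export
filter_cohort <- function(patients, min_months = 8) {
  stopifnot(is.data.frame(patients), "survival_months" %in% names(patients))
  if (!is.numeric(min_months) || length(min_months) != 1L || min_months < 0) {
    stop("`min_months` must be a single nonnegative number.", call. = FALSE)
  }
  out <- dplyr::filter(patients, .data$survival_months > min_months)
  if (nrow(out) == 0L) {
    warning("No patients with survival_months > ", min_months,
      "; returning an empty cohort.",
      call. = FALSE
    )
  }
  out
}

#' Fit drug-effectiveness labels by min-max scaling of survival times
#'
#' Maps survival times onto \[0, 1\] with `(t - min) / (max - min)`, so the
#' shortest included survival gets label 0 and the longest label 1. The label
#' is read as the probability that the drug is effective for that patient;
#' `1 - label` is the failure risk. The fitted min and max are retained so
#' held-out patients can be scaled on the training scale (and clipped to
#' \[0, 1\]).
#'
#' @param times Numeric vector of survival times in months (at least two
#'   distinct values).
#' @param min_months The inclusion floor that produced `times`; stored for
#'   provenance.
#' @return A list of class `labeling_params` with elements `labels` (numeric
#'   vector aligned with `times`), `scale_min`, `scale_max`, `min_months`.
#' @examples
#' fit_effectiveness_labels(c(9, 12, 24))$labels # 0, 0.2, 1
#' @export
fit_effectiveness_labels <- function(times, min_months = 8) {
  if (!is.numeric(times) || length(times) < 2L || anyNA(times)) {
    stop("`times` must be a numeric vector of length >= 2 without NAs.",
      call. = FALSE
    )
  }
  lo <- min(times)
  hi <- max(times)
  if (lo == hi) {
    stop("All survival times are identical; the min-max scale is degenerate.",
      call. = FALSE
    )
  }
  params <- structure(
    list(
      labels = (times - lo) / (hi - lo),
      scale_min = lo,
      scale_max = hi,
      min_months = min_months
    ),
    class = "labeling_params"
  )
  params
}

#' Scale survival times with previously fitted labeling parameters
#'
#' Applies the training-set min-max scale to new times and clips the result
#' to \[0, 1\], so held-out patients never receive labels outside the
#' probability range.
#'
#' @param params A `labeling_params` object from [fit_effectiveness_labels()].
#' @param times Numeric vector of survival times in months.
#' @return Numeric vector of labels in \[0, 1\].
#' @export
apply_effectiveness_labels <- function(params, times) {
  stopifnot(inherits(params, "labeling_params"))
  raw <- (times - params$scale_min) / (params$scale_max - params$scale_min)
  pmin(1, pmax(0, raw))
}

#' Failure risk from an effectiveness label
#'
#' The risk of treatment failure is the complement of the drug-effectiveness
#' probability: `1 - value`.
#'
#' @param label Effectiveness value(s) in \[0, 1\].
#' @return `1 - label`.
#' @export
failure_risk <- function(label) {
  if (any(label < 0 | label > 1, na.rm = TRUE)) {
    stop("Effectiveness labels must lie in [0, 1].", call. = FALSE)
  }
  1 - label
}
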