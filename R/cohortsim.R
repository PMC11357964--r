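#' Simulate a synthetic EGFR-TKI cohort
#'
#' Generates a patient table with the five clinical features used throughout
#' the package (age, gender, mutation abundance, TP53 co-mutation flag,
#' number of co-mutated genes) plus a survival time in months and an event
#' indicator. The demography mimics a typical EGFR-mutant NSCLC cohort:
#' roughly 60% female, ages clipped to 26--86 years.
#'
#' Survival follows a two-level step model: patients whose mutation abundance
#' is at or above `true_threshold` receive `benefit_months` additional
#' expected survival on top of `base_pfs_months`, plus Gaussian noise
#' truncated below at 0.1 months. The step shape reflects the threshold-like
#' contrast between high- and low-abundance patients that motivates the
#' downstream cutpoint search; it is a stand-in generative model, not an
#' estimate of any real cohort's data-generating process.
#'
#' @param n_patients Number of patients to simulate (positive integer).
#' @param seed Integer seed; identical arguments and seed give a
#'   byte-identical table. `NULL` uses the current RNG state.
#' @param female_fraction Probability that a patient is female (gender = 1).
#' @param age_mean,age_sd Mean and SD of the (Gaussian) age distribution,
#'   in years; draws are clipped to \[26, 86\].
#' @param abundance_distribution Distribution of mutation abundance on
#'   \[0, 1\]: `"uniform"` or `"beta"` (shape 2, 2).
#' @param tp53_rate Probability of a TP53 co-mutation.
#' @param comut_mean Mean of the Poisson count of co-mutated genes.
#' @param true_threshold Abundance value at which the survival benefit
#'   switches on.
#' @param base_pfs_months Expected survival (months) below the threshold.
#' @param benefit_months Additional expected survival (months) at or above
#'   the threshold.
#' @param noise_sd SD of the Gaussian noise added to survival, in months.
#' @param censor_rate Probability that a patient is censored (event = 0).
#'
#' @return A tibble with one row per patient and columns `patient_id`,
#'   `age`, `gender`, `mutation_abundance`, `tp53`, `n_comutations`,
#'   `survival_months`, `event`.
#' @examples
#' cohort <- simulate_cohort(100, seed = 1)
#' dplyr::summarise(cohort, mean(gender), mean(survival_months))
#' @export
simulate_cohort <- function(n_patients,
                            seed = NULL,
                            female_fraction = 0.6,
                            age_mean = 60,
                            age_sd = 10,
                            abundance_distribution = c("uniform", "beta"),
                            tp53_rate = 0.4,
                            comut_mean = 3,
                            true_threshold = 0.5,
                            base_pfs_months = 8.4,
                            benefit_months = 8,
                            noise_sd = 2,
                            censor_rate = 0) {
  abundance_distribution <- match.arg(abundance_distribution)
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a single integer >= 1.", call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  for (nm in c("female_fraction", "tp53_rate", "censor_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be in [0, 1].", nm), call. = FALSE)
    }
  }
  if (comut_mean < 0) stop("`comut_mean` must be nonnegative.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative.", call. = FALSE)

  draw <- function() {
    age <- pmin(86, pmax(26, stats::rnorm(n_patients, age_mean, age_sd)))
    gender <- stats::rbinom(n_patients, 1L, female_fraction)
    abundance <- switch(abundance_distribution,
      uniform = stats::runif(n_patients),
      beta = stats::rbeta(n_patients, 2, 2)
    )
    tp53 <- stats::rbinom(n_patients, 1L, tp53_rate)
    n_comut <- stats::rpois(n_patients, comut_mean)
    mu <- base_pfs_months + benefit_months * (abundance >= true_threshold)
    survival <- pmax(0.1, mu + stats::rnorm(n_patients, 0, noise_sd))
    event <- stats::rbinom(n_patients, 1L, 1 - censor_rate)
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      age = age,
      gender = as.integer(gender),
      mutation_abundance = abundance,
      tp53 = as.integer(tp53),
      n_comutations = as.integer(n_comut),
      survival_months = survival,
      event = as.integer(event)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
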