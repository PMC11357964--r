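# milcalib

Calibration-aware multi-instance learning for estimating the risk that a
targeted therapy fails, and for finding the mutation-abundance threshold
that stratifies a cohort into high- and low-risk groups.

## Who this is for

Biostatisticians and translational researchers working with cohorts of
patients on targeted therapy — the motivating setting is EGFR-mutant
non-small cell lung cancer treated with EGFR tyrosine kinase inhibitors —
who need a per-patient *failure-risk* estimate that can be audited with a
standard calibration test, rather than a black-box response score, plus a
data-driven abundance cutoff for risk stratification.

## The method in brief

1. **Labels.** Patients with PFS/TTF strictly above 8 months are included
   and their survival times are min–max scaled to [0, 1]; the scaled value
   is the probability of drug effectiveness, and the failure risk is
   `1 - effectiveness`.
2. **Bags.** Patients are min–max normalised on five clinical features
   (age, gender, mutation abundance, TP53 co-mutation, co-mutation count),
   clustered with k-means (k = 4), and sampled with replacement into bags
   of 1–10 patients per cluster (150/cluster → 600 bags, 250/cluster →
   1,000 bags). A bag's label is the mean of its members' labels.
3. **Model.** A one-hidden-layer network (50 ReLU units, logistic output)
   maps a patient to an effectiveness probability; a bag's prediction is
   the **max** over its instances. Training is gradient descent
   (learning rate 0.001, 200 epochs) on one of five losses: the
   Hosmer–Lemeshow calibration loss

   `HL_s = Σ_q (O_q − E_q)² / E_q + (Ō_q − Ē_q)² / Ē_q`

   over Q = 10 prediction-sorted bins (referred to χ² with Q − 2 df), or
   the MSE / MAE / Huber / log-cosh baselines.
4. **Threshold.** With per-patient risks `d_i` sorted by mutation
   abundance, the split `t` maximising
   `|mean(d_{t+1..n}) − mean(d_{1..t})|` inside a window around the mean
   abundance defines the optimal positive threshold τ (midpoint of the
   flanking abundances). Abundance < τ is high-risk; the strata are
   compared by Welch's t-test on risks and Kaplan–Meier/log-rank on
   survival.

A seeded synthetic-cohort generator (`simulate_cohort()`) provides
five-feature cohorts with a step-shaped survival benefit at a known
abundance threshold, so the whole pipeline is testable without access to
any clinical data.

## Worked example

End-to-end run on a simulated 300-patient cohort (600 training bags,
held-out bags from the 30% held-out patients):

```r
library(milcalib)

res <- run_pipeline(pipeline_config(seed = 1))
res$evaluation
#> # A tibble: 5 × 5
#>   loss       mse hl_statistic hl_df  hl_p
#>   <chr>    <dbl>        <dbl> <int> <dbl>
#> 1 HL      0.0254         4.06     8 0.852
#> 2 MSE     0.0259         5.09     8 0.748
#> 3 MAE     0.0260         4.79     8 0.780
#> 4 HUBER   0.0259         5.09     8 0.748
#> 5 LOGCOSH 0.0259         5.20     8 0.736
```

Every loss passes the held-out Hosmer–Lemeshow test (`hl_p > 0.05`, i.e.
no detectable miscalibration at Q = 10 bins), and on this run the
HL-trained model attains the lowest held-out mean squared error.

Threshold recovery on a cohort simulated with a survival step at abundance
0.5 (risks taken from the fitted labels):

```r
cohort <- simulate_cohort(400, seed = 7, true_threshold = 0.5, benefit_months = 8)
included <- filter_cohort(cohort, 8)
labels <- fit_effectiveness_labels(included$survival_months)
risks <- failure_risk(labels$labels)

thr <- optimal_threshold(included$mutation_abundance, risks)
thr
#> Optimal positive threshold tau = 0.5023 (risk difference 0.4547, split 124 of 155 candidates)

report <- stratify(included, risks, thr$tau)
report
#> Risk stratification at tau = 0.5023
#> # A tibble: 2 × 4
#>   group     n mean_risk mean_survival
#>   <chr> <int>     <dbl>         <dbl>
#> 1 high    124     0.869          9.84
#> 2 low     194     0.415         16.2
```

The search recovers the programmed threshold (τ̂ = 0.502 vs 0.5), and the
high-risk stratum shows the expected pattern: higher mean failure risk
(0.87 vs 0.42) and shorter mean survival (9.8 vs 16.2 months).
`autoplot(report)` draws the Kaplan–Meier curves;
`plot_risk_distribution(report)` the risk box plots; `tidy()`/`glance()`
methods return the fitted objects as tibbles.

A thin command-line wrapper is installed at `inst/cli/milcalib.R`
(subcommands `simulate`, `preprocess`, `train`, `evaluate`, `threshold`,
`stratify`, `run-all`).

## Method notes

See the methods vignette (`vignettes/risk-estimation.Rmd`) for the model's
assumptions, the numerical choices (bin freezing, gradient bounding,
tie-breaks), what the synthetic cohorts do and do not emulate, and known
limitations of the calibration loss as a training signal.
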