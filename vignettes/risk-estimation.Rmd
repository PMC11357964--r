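---
title: "Calibrated multi-instance risk estimation for targeted therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated multi-instance risk estimation for targeted therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(milcalib)
library(dplyr)
```

## The problem

Patients who carry the same actionable mutation — the motivating case is
EGFR-mutant non-small cell lung cancer treated with EGFR tyrosine kinase
inhibitors — respond very differently to the same targeted drug, and a good
part of that heterogeneity tracks the *abundance* of the target mutation in
the tumour sample. Two clinical questions follow. First, can the risk that
the therapy fails be estimated per patient, on a probability scale a
regulator or clinician can interrogate statistically, rather than as an
opaque score? Second, is there a mutation-abundance cutoff at which the
cohort separates into a high-risk and a low-risk stratum?

milcalib addresses both with a deliberately small model: a one-hidden-layer
neural network trained on *bags* of patients (multi-instance learning, MIL)
with a loss derived from the Hosmer–Lemeshow (HL) goodness-of-fit test, so
that the quantity the optimiser minimises is the same quantity a reviewer
would use to audit calibration. After training, a one-dimensional
exhaustive search finds the abundance threshold that maximises the
between-stratum difference in mean predicted failure risk, and the strata
are compared with a Welch t-test on risks and a Kaplan–Meier/log-rank
analysis of survival.

## From survival times to effectiveness labels

Drug effectiveness for an individual patient is unobservable before
treatment; what is recorded is progression-free survival (PFS) or time to
treatment failure (TTF) in months. The labeling stage

1. keeps patients whose survival **strictly exceeds** `min_months`
   (default 8) — `filter_cohort()`;
2. min–max scales the retained survival times onto $[0,1]$ —
   `fit_effectiveness_labels()` — and reads the scaled value as the
   probability that the drug was effective; the failure risk is its
   complement, $d = 1 - \ell$.

Two interpretation points are worth making explicit. The 8-month rule is
implemented as an inclusion floor with a strict inequality; the alternative
reading (a follow-up-maturity criterion) would change which patients enter
the analysis, not any formula downstream, and the floor is configurable.
Held-out patients are always scaled with the *training* minimum and maximum
and clipped to $[0,1]$: test-time survival can exceed the training range
and a probability label must not.

## Bags, clusters and the multi-instance view

Because per-patient effectiveness is unobservable, supervision is attached
to groups. Patients are min–max normalised on five clinical features (age,
gender, mutation abundance, TP53 co-mutation, number of co-mutated genes),
clustered with k-means into $k = 4$ groups, and bags are drawn within a
cluster: each bag contains 1–10 patients sampled with replacement, and its
label is the arithmetic mean of its members' effectiveness labels. With
four clusters, 150 bags per cluster give the 600-bag design and 250 give
the 1,000-bag design. The bag-size distribution is uniform on
$\{1,\dots,10\}$ — the source design states only the range — and bags never
mix clusters.

Clustering before bagging keeps bags internally homogeneous, which is what
makes the mean a sensible bag label. No feature is dropped before
clustering: the upstream analysis alludes to a feature-selection step it
never specifies, so the package clusters on all five features and leaves
selection to the user.

```{r bags}
cohort <- simulate_cohort(300, seed = 102)
included <- filter_cohort(cohort, 8)
labels <- fit_effectiveness_labels(included$survival_months)
features <- normalize_features(included)
clusters <- cluster_patients(features, k = 4, seed = 1)
bags <- make_bags(features, labels$labels, clusters,
  bags_per_cluster = 150, seed = 2
)
bags
```

## The network and its losses

The network is intentionally minimal: $p = 5$ inputs, one hidden layer of
50 rectified-linear units, a logistic output, so every instance output lies
in $(0,1)$ and is directly a probability. The bag prediction is the
**maximum** over its instances' outputs (max pooling), the classical MIL
aggregation; gradients flow through the maximal instance only. Training is
plain gradient descent with learning rate 0.001 for 200 epochs (the
defaults), with an optional early stop once the *global error* — the sum of
per-bag squared errors $E_i = \tfrac12 (o_i - L_i)^2$ — falls below a
threshold.

Five losses are available. Four are classical regression baselines on the
bag residual $r_i = o_i - L_i$: squared error $\sum \tfrac12 r_i^2$,
absolute error $\sum |r_i|$, Huber with transition $\delta$ (selected by
5-fold cross-validation over bags when unset), and log-cosh. The fifth is
the calibration loss: bags are sorted by prediction into $Q = 10$
near-equal groups (decile-of-risk binning), and the loss is the HL
statistic

$$
HL_s = \sum_{q=1}^{Q}
\frac{(O_q - E_q)^2}{E_q} +
\frac{(\bar O_q - \bar E_q)^2}{\bar E_q},
$$

where $O_q$ and $E_q$ are the observed and expected "effective" mass in
group $q$ (sums of bag labels and of bag predictions) and the barred
quantities are the complements. With 0/1 labels this is exactly the
classical HL table; with continuous labels in $[0,1]$ each bag contributes
its label mass, and the statistic still vanishes exactly at perfect
calibration. The statistic is referred to a $\chi^2_{Q-2}$ distribution;
$p > 0.05$ is read as "no detectable miscalibration".

### Numerical choices

* **Bin freezing.** The sort underlying the binning makes the HL loss
  non-differentiable at bin boundaries; bin memberships are frozen within
  each update step (straight-through past the sort), making the loss
  piecewise smooth. Any bin with zero expected mass on either side would
  contribute its bags' squared-error terms instead; with a logistic output
  this branch is unreachable, but it is coded and tested.
* **Gradient bounding.** The HL gradient with respect to a single bag's
  prediction grows like the reciprocal of a bin's expected mass and is
  unbounded near saturated bins; unbounded steps overshoot at any fixed
  learning rate. The per-bag output gradient is therefore clipped to
  $[-1, 1]$ — the largest magnitude any baseline loss can produce
  ($|\partial\,\mathrm{MAE}/\partial o| = 1$) — before backpropagation.
* **Update mode.** Weight updates are full-batch by default: with the
  per-epoch gradient frozen, a sweep of per-bag updates is first-order
  identical to one batch step, and the batch form is deterministic and
  vectorises over bags. A `per_bag` sweep mode is available for users who
  want the sequential behaviour of the original pseudocode.
* **Ties and degeneracies.** Prediction ties in binning are broken by
  input order; constant feature columns normalise to 0 with a warning; an
  all-identical survival vector is a hard error (the min–max scale is
  undefined); predictions are clamped away from 0 and 1 by $10^{-12}$
  before entering any HL table.

```{r train}
fit <- train_mil(bags, loss = "HL", epochs = 200, seed = 3)
glance(fit)
```

## Threshold search and stratification

Per-patient risks are singleton-bag predictions complemented to failure
risks. Sorting patients by mutation abundance, every split $t$ inside a
window of half-width `margin` around the mean abundance is scored by

$$
\mathrm{diff}(t) = \left|
\frac{1}{n-t}\sum_{i > t} d_i - \frac{1}{t}\sum_{i \le t} d_i
\right|,
$$

and the threshold $\tau$ is the midpoint between the abundances flanking
the maximising split, so no training patient sits on the boundary. Ties go
to the smallest split. The default `margin` is a quarter of the abundance
range: the window exists because extreme splits (one patient against the
rest) can produce spuriously large mean differences, and the source design
brackets the search around the abundance mean without stating a width;
`margin = Inf` is supported and is what the brute-force equivalence tests
use. Patients with abundance **below** $\tau$ form the high-risk stratum;
the boundary itself is low-risk.

```{r threshold}
risks <- predict_patient_risk(fit, included, features)
thr <- optimal_threshold(included$mutation_abundance, risks$risk)
tidy(thr)
report <- stratify(included, risks$risk, thr$tau)
tidy(report)
```

The stratified comparison reports the Welch two-sample t-test on the
predicted risks and the two-group log-rank test with Kaplan–Meier curves
(`autoplot(report)`); both wrap the standard `stats` and `survival`
machinery. Event indicators default to 1 — the labeling model treats
PFS/TTF as fully observed — but the survival machinery accepts censoring.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` produces the five-feature schema with a demography
typical of the motivating cohorts: about 60% female, Gaussian ages clipped
to 26–86 years, uniform mutation abundance on $[0,1]$, a 40% TP53
co-mutation rate, Poisson co-mutation counts (mean 3). Survival follows a
two-level step: `base_pfs_months` (default 8.4) plus `benefit_months`
(default 8) once abundance reaches `true_threshold` (default 0.5), plus
Gaussian noise (`noise_sd`, default 2 months — a realistic PFS dispersion
for this setting) truncated below at 0.1 months. The step-plus-noise form
was chosen because the phenomenon being modelled is precisely a
threshold-like contrast in survival by abundance; censoring defaults to
none because the labeling model has no notion of it, with a `censor_rate`
knob for exercising the Kaplan–Meier machinery.

No generative model for the real cohorts is published, so all of these
distributional choices are stand-ins. The simulator does **not** emulate
correlated clinical covariates, informative censoring, measurement error in
abundance, cohort batch effects, or any sequencing-level process.
Consequently, passing tests demonstrate that the algorithms recover the
structure they assume — not that the model is adequate for any particular
real cohort.

Default problem sizes used throughout the package's own experiments:
cohorts of 300 patients (400 for threshold recovery), 600 training bags,
200 held-out bags built from the 30% held-out patients (transformed with
the training normalisation and assigned to the nearest training centroid),
200 training epochs. These are the package's standard working sizes; all
are configurable.

## Known limitations

* **The calibration loss is under-identified as a training signal.** The
  decile-binned HL statistic depends on predictions only through
  bin-level sums taken in the predictions' own sort order. A model that
  predicts close to the overall label mean everywhere is a near-minimiser,
  and within a bin every bag receives the same gradient, so the loss
  exerts no pressure toward correct per-bag *ranking*. In the package's
  acceptance experiments the HL-trained model passes the held-out HL test,
  but its held-out HL statistic is typically *larger* than that of the
  squared-error baselines, which shape individual predictions directly.
  Users wanting both calibration and discrimination should compare losses
  on held-out bags (the evaluation report does this by default) rather
  than assume the calibration loss dominates.
* The HL test's $\chi^2_{Q-2}$ reference assumes predictions estimated
  from the data under a well-specified model; for predictions fixed a
  priori the statistic is closer to $\chi^2_Q$ and the reported p-value is
  conservative in one direction. The null-behaviour test therefore
  simulates fitted logistic models, the setting in which the $Q-2$
  reference is exact.
* The threshold search assumes a single change point in risk along
  abundance and applies no multiplicity correction across candidate
  splits, mirroring the source procedure.
* Training is plain gradient descent at a fixed learning rate; no
  momentum, adaptivity, or architecture search is attempted, by design.
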