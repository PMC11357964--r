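# Shared fixtures, built in code at test time.

# A feature_matrix wrapping an arbitrary numeric matrix (already on [0,1]).
fm_from_matrix <- function(x) {
  x <- as.matrix(x)
  structure(
    list(
      values = x,
      norm_params = tibble::tibble(
        feature = paste0("f", seq_len(ncol(x))),
        min = rep(0, ncol(x)),
        max = rep(1, ncol(x))
      )
    ),
    class = "feature_matrix"
  )
}

# A small bag dataset over random instances with the given bag sizes.
toy_bag_dataset <- function(n_instances = 20, n_features = 5, n_bags = 10,
                            max_size = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n_instances * n_features), n_instances, n_features)
    labels <- runif(n_instances)
    sizes <- sample.int(max_size, n_bags, replace = TRUE)
    rows <- lapply(sizes, function(m) sample.int(n_instances, m, replace = TRUE))
    bags <- tibble::tibble(
      bag_id = sprintf("B%03d", seq_len(n_bags)),
      cluster = 1L,
      size = sizes,
      instance_rows = rows,
      instance_labels = lapply(rows, function(r) labels[r]),
      label = vapply(rows, function(r) mean(labels[r]), numeric(1))
    )
    structure(
      list(
        bags = bags, features = fm_from_matrix(x), labels = labels,
        bags_per_cluster = n_bags, seed = seed
      ),
      class = "bag_dataset"
    )
  })
}

# A random valid Hosmer-Lemeshow table (positive expected masses).
random_hl_table <- function(Q = 5) {
  tibble::tibble(
    group = seq_len(Q),
    n = rep(10, Q),
    observed_A = runif(Q, 0, 10),
    expected_A = runif(Q, 0.5, 9.5),
    observed_not_A = runif(Q, 0, 10),
    expected_not_A = runif(Q, 0.5, 9.5)
  )
}

# Brute-force HL statistic: direct term-by-term evaluation.
hl_brute_force <- function(tab) {
  total <- 0
  for (q in seq_len(nrow(tab))) {
    total <- total +
      (tab$observed_A[q] - tab$expected_A[q])^2 / tab$expected_A[q] +
      (tab$observed_not_A[q] - tab$expected_not_A[q])^2 / tab$expected_not_A[q]
  }
  total
}

# End-to-end preprocessing of a simulated cohort up to train/held-out bag
# datasets, mirroring the pipeline stages with explicit seeds.
prepared_cohort <- function(n = 300, cohort_seed = 102, split_seed = 202,
                            bags_per_cluster = 150, heldout_per_cluster = 50,
                            ...) {
  cohort <- simulate_cohort(n, seed = cohort_seed, ...)
  inc <- filter_cohort(cohort, 8)
  lab <- fit_effectiveness_labels(inc$survival_months)
  ntot <- nrow(inc)
  tr <- withr::with_seed(split_seed, sort(sample.int(ntot, round(0.7 * ntot))))
  te <- setdiff(seq_len(ntot), tr)
  f <- normalize_features(inc[tr, ])
  a <- cluster_patients(f, 4, seed = split_seed + 1)
  train_bags <- make_bags(f, lab$labels[tr], a, bags_per_cluster,
    seed = split_seed + 2
  )
  hov <- apply_normalization(f, inc[te, ])
  hof <- fm_from_matrix(hov)
  hof$norm_params <- f$norm_params
  cent <- milcalib:::cluster_centroids(f$values, a)
  hoa <- milcalib:::assign_to_clusters(hov, cent)
  hoa <- match(hoa, sort(unique(hoa)))
  heldout_bags <- make_bags(hof, lab$labels[te], hoa, heldout_per_cluster,
    seed = split_seed + 3
  )
  list(
    cohort = cohort, included = inc, labeling = lab,
    train_idx = tr, test_idx = te, features = f, assignments = a,
    train_bags = train_bags, heldout_bags = heldout_bags
  )
}

heldout_hl_statistic <- function(net, heldout_bags, Q = 10) {
  p <- milcalib:::clamp01(predict_bags(net, heldout_bags))
  hl_test(p, heldout_bags$bags$label, Q)$statistic
}
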