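#' Build a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one list. All
#' randomness flows from the single root `seed`, which is split into fixed
#' per-stage offsets so each stage is independently reproducible.
#'
#' @param input Path to a patient CSV, or `NULL` to simulate a cohort.
#' @param output_dir Directory for artifacts (created if missing); `NULL`
#'   skips writing and returns results in memory only.
#' @param simulate Named list of [simulate_cohort()] arguments (used when
#'   `input` is `NULL`); `n_patients` defaults to 300.
#' @param min_months Survival inclusion floor in months.
#' @param k Number of k-means clusters.
#' @param bags_per_cluster Bags drawn per cluster for the training set.
#' @param heldout_bags_per_cluster Bags per cluster for the held-out set.
#' @param train_fraction Fraction of patients assigned to training.
#' @param loss Training loss for the primary model.
#' @param hidden_dim,learning_rate,epochs,global_error_threshold,Q
#'   Training hyperparameters, see [train_mil()].
#' @param huber_delta Huber delta, or `NULL` to select by cross-validation
#'   when the Huber loss is evaluated.
#' @param margin Threshold-search half-width; `NULL` uses the default
#'   quarter-range rule of [optimal_threshold()].
#' @param evaluate_all_losses Whether the evaluation report compares all
#'   five losses (TRUE) or only the configured one.
#' @param seed Root seed.
#' @param verbose Print stage progress.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            output_dir = NULL,
                            simulate = list(),
                            min_months = 8,
                            k = 4,
                            bags_per_cluster = 150,
                            heldout_bags_per_cluster = 50,
                            train_fraction = 0.7,
                            loss = "HL",
                            hidden_dim = 50,
                            learning_rate = 0.001,
                            epochs = 200,
                            global_error_threshold = 0,
                            Q = 10,
                            huber_delta = 1,
                            margin = NULL,
                            evaluate_all_losses = TRUE,
                            seed = 1,
                            verbose = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, split = 202L, cluster = 303L, bags = 404L,
    net = 505L, heldout = 606L, huber = 707L
  )
  as.integer(seed) + offsets[[stage]]
}

# Nearest-centroid assignment of new rows to training clusters.
assign_to_clusters <- function(x, centroids) {
  d2 <- vapply(seq_len(nrow(centroids)), function(j) {
    rowSums(sweep(x, 2, centroids[j, ], "-")^2)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

cluster_centroids <- function(values, assignments) {
  ks <- sort(unique(assignments))
  t(vapply(ks, function(k) colMeans(values[assignments == k, , drop = FALSE]),
    numeric(ncol(values))
  ))
}

#' Run the full risk-estimation pipeline
#'
#' Orchestrates, in order: cohort loading (or simulation), the survival
#' inclusion filter, min-max effectiveness labeling, a patient-level
#' train/held-out split, feature normalisation and k-means clustering of
#' the training patients, bag sampling on both splits (held-out patients
#' are transformed with the training normalisation and assigned to the
#' nearest training cluster), network training, an evaluation report
#' (held-out MSE, HL statistic and p-value, for every loss when
#' `evaluate_all_losses`), the optimal mutation-abundance threshold from
#' training-patient risks, and the threshold-stratified comparison of the
#' whole included cohort. When `output_dir` is set, every artifact is
#' written with the config hash and all stage seeds embedded.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with `patients`, `included`, `labeling`,
#'   `split`, `features`, `assignments`, `train_bags`, `heldout_bags`,
#'   `fit`, `evaluation`, `threshold`, `stratification`, `seeds`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, ...) {
    if (isTRUE(config$verbose)) message("[", stage, "] ", ...)
  }
  seeds <- vapply(
    c("simulate", "split", "cluster", "bags", "net", "heldout", "huber"),
    function(s) stage_seed(config$seed, s), integer(1)
  )
  config_hash <- rlang::hash(
    config[setdiff(names(config), c("verbose", "output_dir"))]
  )

  # --- cohort ---------------------------------------------------------
  patients <- if (is.null(config$input)) {
    sim_args <- utils::modifyList(
      list(n_patients = 300, seed = seeds[["simulate"]]),
      config$simulate
    )
    say("simulate", "cohort of ", sim_args$n_patients)
    do.call(simulate_cohort, sim_args)
  } else {
    say("load", config$input)
    load_patient_table(config$input)
  }

  # --- labeling -------------------------------------------------------
  included <- filter_cohort(patients, config$min_months)
  if (nrow(included) < 10L) {
    stop("Stage labeling: only ", nrow(included),
      " patients pass the survival filter; need at least 10.",
      call. = FALSE
    )
  }
  labeling <- fit_effectiveness_labels(
    included$survival_months,
    min_months = config$min_months
  )
  say("labeling", nrow(included), " patients included")

  # --- split ----------------------------------------------------------
  n <- nrow(included)
  n_train <- max(2L, round(config$train_fraction * n))
  train_idx <- withr::with_seed(
    seeds[["split"]], sort(sample.int(n, n_train))
  )
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- included[train_idx, ]
  heldout <- included[test_idx, ]
  say("split", length(train_idx), " train / ", length(test_idx), " held-out")

  # --- preprocessing & bagging ---------------------------------------
  features <- normalize_features(train)
  assignments <- cluster_patients(features, k = config$k,
    seed = seeds[["cluster"]]
  )
  train_labels <- labeling$labels[train_idx]
  train_bags <- make_bags(features, train_labels, assignments,
    bags_per_cluster = config$bags_per_cluster, seed = seeds[["bags"]]
  )
  say("bags", nrow(train_bags$bags), " training bags")

  heldout_bags <- NULL
  if (nrow(heldout) >= 2L) {
    ho_values <- apply_normalization(features, heldout)
    ho_features <- structure(
      list(values = ho_values, norm_params = features$norm_params),
      class = "feature_matrix"
    )
    centroids <- cluster_centroids(features$values, assignments)
    ho_assign <- assign_to_clusters(ho_values, centroids)
    ho_assign <- match(ho_assign, sort(unique(ho_assign))) # drop empty ids
    heldout_bags <- make_bags(ho_features,
      labeling$labels[test_idx], ho_assign,
      bags_per_cluster = config$heldout_bags_per_cluster,
      seed = seeds[["heldout"]]
    )
    say("bags", nrow(heldout_bags$bags), " held-out bags")
  }

  # --- training -------------------------------------------------------
  train_one <- function(loss) {
    delta <- config$huber_delta
    if (identical(toupper(loss), "HUBER") && is.null(delta)) {
      delta <- select_huber_delta(train_bags,
        seed = seeds[["huber"]],
        hidden_dim = config$hidden_dim,
        learning_rate = config$learning_rate,
        epochs = config$epochs, Q = config$Q
      )
      say("train", "cross-validated huber delta = ", delta)
    }
    train_mil(train_bags,
      loss = loss,
      hidden_dim = config$hidden_dim,
      learning_rate = config$learning_rate,
      epochs = config$epochs,
      global_error_threshold = config$global_error_threshold,
      Q = config$Q,
      huber_delta = if (is.null(delta)) 1 else delta,
      seed = seeds[["net"]]
    )
  }
  fit <- train_one(config$loss)
  say("train", "final GlobalErr = ",
    signif(fit$history$global_err[fit$epochs_run], 4)
  )

  # --- evaluation -----------------------------------------------------
  eval_losses <- if (isTRUE(config$evaluate_all_losses)) {
    mil_losses
  } else {
    toupper(config$loss)
  }
  eval_set <- if (!is.null(heldout_bags)) heldout_bags else train_bags
  evaluation <- purrr::map_dfr(eval_losses, function(l) {
    f <- if (identical(l, toupper(config$loss))) fit else train_one(l)
    p <- clamp01(predict_bags(f$network, eval_set))
    yv <- eval_set$bags$label
    hl <- hl_test(p, yv, Q = config$Q)
    tibble::tibble(
      loss = l,
      mse = mean((p - yv)^2),
      hl_statistic = hl$statistic,
      hl_df = hl$df,
      hl_p = hl$p_value
    )
  })
  say("evaluate", "held-out HL p for ", toupper(config$loss), " = ",
    signif(evaluation$hl_p[evaluation$loss == toupper(config$loss)], 3)
  )

  # --- threshold ------------------------------------------------------
  train_risk <- predict_patient_risk(fit, train, features)$risk
  thr_args <- list(abundances = train$mutation_abundance, risks = train_risk)
  if (!is.null(config$margin)) thr_args$margin <- config$margin
  threshold <- do.call(optimal_threshold, thr_args)
  say("threshold", "tau = ", signif(threshold$tau, 4))

  # --- stratification -------------------------------------------------
  all_risk <- predict_patient_risk(fit, included, features)$risk
  stratification <- stratify(included, all_risk, threshold$tau)

  result <- list(
    patients = patients,
    included = included,
    labeling = labeling,
    split = list(train_idx = train_idx, test_idx = test_idx),
    features = features,
    assignments = assignments,
    train_bags = train_bags,
    heldout_bags = heldout_bags,
    fit = fit,
    evaluation = evaluation,
    threshold = threshold,
    stratification = stratification,
    seeds = as.list(seeds),
    config_hash = config_hash
  )

  if (!is.null(config$output_dir)) {
    write_pipeline_artifacts(result, config)
  }
  invisible(result)
}

write_pipeline_artifacts <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(config$output_dir, name)
  meta <- list(config_hash = result$config_hash, seeds = result$seeds)

  if (is.null(config$input)) {
    write_patient_table(result$patients, p("patients.csv"))
  }
  jsonlite::write_json(
    c(meta, list(
      scale_min = result$labeling$scale_min,
      scale_max = result$labeling$scale_max,
      min_months = result$labeling$min_months
    )),
    p("labeling.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_feature_matrix(result$features, params_path = p("feature_norm.csv"))
  save_bag_dataset(result$train_bags, p("bags_train.jsonl"),
    patient_ids = result$included$patient_id[result$split$train_idx]
  )
  if (!is.null(result$heldout_bags)) {
    save_bag_dataset(result$heldout_bags, p("bags_heldout.jsonl"),
      patient_ids = result$included$patient_id[result$split$test_idx]
    )
  }
  save_model(result$fit, p("model.json"),
    features = result$features, labeling = result$labeling
  )
  utils::write.csv(result$fit$history, p("history.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(meta, list(evaluation = result$evaluation)),
    p("evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    c(meta, result$threshold[c(
      "tau", "diff", "split_index", "candidates_considered", "margin",
      "degenerate"
    )]),
    p("threshold.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  s <- result$stratification
  jsonlite::write_json(
    c(meta, list(
      tau = s$tau, groups = s$groups,
      t_statistic = s$t_statistic, t_pvalue = s$t_pvalue,
      logrank_statistic = s$logrank_statistic,
      logrank_pvalue = s$logrank_pvalue
    )),
    p("stratification.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(s$km_curves)) {
    utils::write.csv(s$km_curves, p("km_curves.csv"), row.names = FALSE)
  }
  invisible(config$output_dir)
}
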