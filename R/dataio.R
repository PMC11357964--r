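patient_required_cols <- c(
  "patient_id", "age", "gender", "mutation_abundance", "tp53",
  "n_comutations", "survival_months"
)

#' Read and validate a patient table
#'
#' Reads the standard patient CSV (columns `patient_id`, `age`, `gender`,
#' `mutation_abundance`, `tp53`, `n_comutations`, `survival_months`, and
#' optionally `event`), preserving row order. Binary columns must be 0/1,
#' survival must be positive, and duplicate patient ids are rejected; the
#' offending row and column are named in every validation error.
#'
#' @param path Path to the CSV file.
#' @return A patient tibble; a missing `event` column is filled with 1
#'   (event observed).
#' @export
load_patient_table <- function(path) {
  if (!file.exists(path)) {
    stop("Patient table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(patient_required_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("Patient table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!("event" %in% names(raw))) raw$event <- 1L
  numeric_cols <- c(
    "age", "gender", "mutation_abundance", "tp53", "n_comutations",
    "survival_months", "event"
  )
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop("Unparseable value in column `", col, "`, row ", bad[1], ".",
        call. = FALSE
      )
    }
    raw[[col]] <- v
  }
  for (col in c("gender", "tp53", "event")) {
    bad <- which(!(raw[[col]] %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop("Column `", col, "` must be 0/1; row ", bad[1], " has value ",
        raw[[col]][bad[1]], ".",
        call. = FALSE
      )
    }
    raw[[col]] <- as.integer(raw[[col]])
  }
  bad <- which(raw$survival_months <= 0)
  if (length(bad) > 0L) {
    stop("`survival_months` must be positive; row ", bad[1], ".",
      call. = FALSE
    )
  }
  dup <- duplicated(raw$patient_id)
  if (any(dup)) {
    stop("Duplicate patient_id: ", raw$patient_id[which(dup)[1]], ".",
      call. = FALSE
    )
  }
  bad <- which(raw$mutation_abundance < 0)
  if (length(bad) > 0L) {
    stop("`mutation_abundance` must be nonnegative; row ", bad[1], ".",
      call. = FALSE
    )
  }
  raw$n_comutations <- as.integer(raw$n_comutations)
  tibble::as_tibble(raw[, c(patient_required_cols, "event")])
}

#' Write a patient table to CSV
#'
#' @param patients Patient tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a bag dataset to JSON lines
#'
#' One bag per line: `bag_id`, `cluster`, `instance_rows` (1-based row
#' indices into the feature matrix), `instance_patient_ids` (when supplied),
#' `instance_labels`, `label`.
#'
#' @param dataset A `bag_dataset`.
#' @param path Output path (`.jsonl`).
#' @param patient_ids Optional patient ids aligned with the feature rows.
#' @return `path`, invisibly.
#' @export
save_bag_dataset <- function(dataset, path, patient_ids = NULL) {
  stopifnot(inherits(dataset, "bag_dataset"))
  lines <- purrr::pmap_chr(
    dataset$bags[, c("bag_id", "cluster", "instance_rows", "instance_labels", "label")],
    function(bag_id, cluster, instance_rows, instance_labels, label) {
      rec <- list(
        bag_id = bag_id,
        cluster = cluster,
        instance_rows = instance_rows,
        instance_labels = instance_labels,
        label = label
      )
      if (!is.null(patient_ids)) {
        rec$instance_patient_ids <- patient_ids[instance_rows]
      }
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a bag dataset from JSON lines
#'
#' @param path `.jsonl` file from [save_bag_dataset()].
#' @param features The `feature_matrix` the bag rows index into.
#' @param labels Instance labels aligned with the feature rows.
#' @return A `bag_dataset`.
#' @export
load_bag_dataset <- function(path, features, labels) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  bags <- tibble::tibble(
    bag_id = vapply(recs, `[[`, character(1), "bag_id"),
    cluster = vapply(recs, `[[`, numeric(1), "cluster"),
    size = vapply(recs, function(r) length(r$instance_rows), integer(1)),
    instance_rows = lapply(recs, function(r) as.integer(r$instance_rows)),
    instance_labels = lapply(recs, function(r) as.numeric(r$instance_labels)),
    label = vapply(recs, `[[`, numeric(1), "label")
  )
  structure(
    list(
      bags = bags, features = features, labels = labels,
      bags_per_cluster = NA_integer_, seed = NA_integer_
    ),
    class = "bag_dataset"
  )
}

#' Write a fitted feature normalisation to CSV
#'
#' @param features A `feature_matrix`.
#' @param values_path CSV for the normalised values (optional, `NULL` skips).
#' @param params_path CSV for the per-feature min/max.
#' @return `params_path`, invisibly.
#' @export
write_feature_matrix <- function(features, values_path = NULL, params_path) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!is.null(values_path)) {
    utils::write.csv(as.data.frame(features$values), values_path,
      row.names = FALSE
    )
  }
  utils::write.csv(features$norm_params, params_path, row.names = FALSE)
  invisible(params_path)
}

#' Read a feature normalisation written by [write_feature_matrix()]
#'
#' @param params_path CSV of per-feature min/max.
#' @param values_path Optional CSV of normalised values.
#' @return A `feature_matrix` (with `values = NULL` when no values file is
#'   given; sufficient for [apply_normalization()]).
#' @export
read_feature_matrix <- function(params_path, values_path = NULL) {
  params <- tibble::as_tibble(utils::read.csv(params_path))
  values <- if (!is.null(values_path)) {
    as.matrix(utils::read.csv(values_path))
  }
  structure(
    list(values = values, norm_params = params),
    class = "feature_matrix"
  )
}

#' Save a trained model (and its preprocessing) as JSON
#'
#' Stores the network weights and dimensions, training metadata, the
#' feature normalisation, and the labeling scale, so held-out patients can
#' be scored from the artifact alone.
#'
#' @param fit A `mil_fit`.
#' @param path Output JSON path.
#' @param features Optional training `feature_matrix` (norm params stored).
#' @param labeling Optional `labeling_params`.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path, features = NULL, labeling = NULL) {
  stopifnot(inherits(fit, "mil_fit"))
  net <- fit$network
  obj <- list(
    network = list(
      W1 = net$W1, b1 = net$b1, w2 = net$w2, b2 = net$b2,
      input_dim = net$input_dim, hidden_dim = net$hidden_dim,
      seed = net$seed
    ),
    loss = fit$loss,
    learning_rate = fit$learning_rate,
    epochs = fit$epochs,
    epochs_run = fit$epochs_run,
    Q = fit$Q,
    huber_delta = fit$huber_delta,
    seed = fit$seed
  )
  if (!is.null(features)) obj$norm_params <- features$norm_params
  if (!is.null(labeling)) {
    obj$labeling <- list(
      scale_min = labeling$scale_min,
      scale_max = labeling$scale_max,
      min_months = labeling$min_months
    )
  }
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON artifact path.
#' @return List with `network` (a `mil_network`), `features` (a
#'   `feature_matrix` carrying the stored normalisation, or `NULL`),
#'   `labeling` (a `labeling_params` or `NULL`), and the stored metadata.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  net <- structure(
    list(
      W1 = as.matrix(obj$network$W1),
      b1 = as.numeric(obj$network$b1),
      w2 = as.numeric(obj$network$w2),
      b2 = as.numeric(obj$network$b2),
      input_dim = as.integer(obj$network$input_dim),
      hidden_dim = as.integer(obj$network$hidden_dim),
      seed = as.integer(obj$network$seed)
    ),
    class = "mil_network"
  )
  features <- if (!is.null(obj$norm_params)) {
    structure(
      list(values = NULL, norm_params = tibble::as_tibble(obj$norm_params)),
      class = "feature_matrix"
    )
  }
  labeling <- if (!is.null(obj$labeling)) {
    structure(
      list(
        labels = NULL,
        scale_min = obj$labeling$scale_min,
        scale_max = obj$labeling$scale_max,
        min_months = obj$labeling$min_months
      ),
      class = "labeling_params"
    )
  }
  list(
    network = net, features = features, labeling = labeling,
    loss = obj$loss, Q = obj$Q, seed = obj$seed
  )
}
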