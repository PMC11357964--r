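#' Clinical feature columns used for clustering and the network input
#' @keywords internal
mil_feature_cols <- function() {
  c("age", "gender", "mutation_abundance", "tp53", "n_comutations")
}

#' Min-max normalise the clinical feature matrix
#'
#' Scales each of the five clinical features (age, gender, mutation
#' abundance, TP53 flag, number of co-mutations) to \[0, 1\] by column-wise
#' min-max normalisation. Binary columns are left on their natural 0/1 scale
#' by the same formula. Constant columns map to 0 with a warning. The
#' per-column minima and maxima are retained so held-out patients can be
#' transformed onto the training scale with [apply_normalization()].
#'
#' @param patients Patient tibble containing `feature_cols`.
#' @param feature_cols Character vector of feature columns (default the
#'   five-feature clinical schema).
#' @return A `feature_matrix` object: list with `values` (numeric matrix,
#'   one row per patient) and `norm_params` (tibble of feature, min, max).
#' @export
normalize_features <- function(patients, feature_cols = mil_feature_cols()) {
  stopifnot(is.data.frame(patients))
  missing_cols <- setdiff(feature_cols, names(patients))
  if (length(missing_cols) > 0L) {
    stop("Missing feature column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(patients) < 2L) {
    stop("Need at least two patients to fit a normalisation.", call. = FALSE)
  }
  x <- as.matrix(patients[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  for (j in seq_along(feature_cols)) {
    if (anyNA(x[, j])) {
      stop("Missing values in feature `", feature_cols[j], "`.", call. = FALSE)
    }
  }
  mins <- unname(apply(x, 2, min))
  maxs <- unname(apply(x, 2, max))
  constant <- maxs == mins
  if (any(constant)) {
    warning("Constant feature(s) mapped to 0: ",
      paste(feature_cols[constant], collapse = ", "),
      call. = FALSE
    )
  }
  params <- tibble::tibble(feature = feature_cols, min = mins, max = maxs)
  structure(
    list(
      values = scale_by_params(x, params),
      norm_params = params
    ),
    class = "feature_matrix"
  )
}

scale_by_params <- function(x, params) {
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

#' Transform new patients with a fitted normalisation
#'
#' @param features A `feature_matrix` from [normalize_features()].
#' @param patients Patient tibble with the same feature columns.
#' @return Numeric matrix of transformed features (training scale, not
#'   clipped; held-out values may fall slightly outside \[0, 1\]).
#' @export
apply_normalization <- function(features, patients) {
  stopifnot(inherits(features, "feature_matrix"))
  cols <- features$norm_params$feature
  missing_cols <- setdiff(cols, names(patients))
  if (length(missing_cols) > 0L) {
    stop("Missing feature column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- as.matrix(patients[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  scale_by_params(x, features$norm_params)
}

#' Cluster patients with k-means on normalised features
#'
#' Groups patients into `k` clusters (4 by default) by k-means on the
#' min-max-normalised feature matrix, with 10 random restarts under a fixed
#' seed so the assignment is reproducible.
#'
#' @param features A `feature_matrix` from [normalize_features()].
#' @param k Number of clusters.
#' @param seed Integer seed for the restarts.
#' @return Integer vector of cluster assignments in `1:k`, one per patient.
#' @export
cluster_patients <- function(features, k = 4, seed = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  n <- nrow(features$values)
  if (n < k) {
    stop("Cannot form ", k, " clusters from ", n, " patients.", call. = FALSE)
  }
  if (k == 1L) {
    return(rep(1L, n))
  }
  fit <- withr::with_seed(
    as.integer(seed),
    stats::kmeans(features$values, centers = k, nstart = 10, iter.max = 100)
  )
  as.integer(fit$cluster)
}

#' Sample multi-instance bags from patient clusters
#'
#' Draws `bags_per_cluster` bags from every cluster. Each bag's size is
#' uniform on `min_size:max_size` (1--10 by default) and its instances are
#' drawn with replacement from the patients of a single cluster; the bag
#' label is the arithmetic mean of the member instances' effectiveness
#' labels. With 4 clusters, `bags_per_cluster = 150` gives the 600-bag
#' design and 250 gives the 1,000-bag design.
#'
#' @param features A `feature_matrix` for the patients being bagged.
#' @param labels Numeric effectiveness labels aligned with the feature rows.
#' @param assignments Integer cluster assignment per patient.
#' @param bags_per_cluster Number of bags drawn from each cluster.
#' @param min_size,max_size Bag size range (instances per bag).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `bag_dataset`: list with `bags` (tibble: `bag_id`, `cluster`,
#'   `size`, list-columns `instance_rows` and `instance_labels`, `label`),
#'   `features`, `labels`, `bags_per_cluster`, `seed`.
#' @export
make_bags <- function(features, labels, assignments, bags_per_cluster,
                      min_size = 1, max_size = 10, seed = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  n <- nrow(features$values)
  if (length(labels) != n || length(assignments) != n) {
    stop("`labels` and `assignments` must align with the feature rows.",
      call. = FALSE
    )
  }
  if (any(labels < 0 | labels > 1)) {
    stop("Effectiveness labels must lie in [0, 1].", call. = FALSE)
  }
  if (bags_per_cluster < 1) {
    stop("`bags_per_cluster` must be >= 1.", call. = FALSE)
  }
  clusters <- sort(unique(assignments))
  empty <- setdiff(seq_len(max(assignments)), clusters)
  if (length(empty) > 0L) {
    stop("Cluster(s) ", paste(empty, collapse = ", "), " are empty; ",
      "re-cluster or lower k before bagging.",
      call. = FALSE
    )
  }
  bags <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(clusters, function(cl) {
      members <- which(assignments == cl)
      sizes <- sample(seq.int(min_size, max_size), bags_per_cluster,
        replace = TRUE
      )
      rows <- purrr::map(sizes, function(m) {
        members[sample.int(length(members), m, replace = TRUE)]
      })
      tibble::tibble(
        cluster = cl,
        size = sizes,
        instance_rows = rows,
        instance_labels = purrr::map(rows, ~ labels[.x]),
        label = purrr::map_dbl(instance_labels, mean)
      )
    })
  })
  bags <- dplyr::mutate(bags,
    bag_id = sprintf("B%04d", dplyr::row_number()),
    .before = 1
  )
  structure(
    list(
      bags = bags,
      features = features,
      labels = labels,
      bags_per_cluster = bags_per_cluster,
      seed = as.integer(seed)
    ),
    class = "bag_dataset"
  )
}

#' @export
print.bag_dataset <- function(x, ...) {
  cat(
    "<bag_dataset> ", nrow(x$bags), " bags from ",
    length(unique(x$bags$cluster)), " clusters (",
    x$bags_per_cluster, " per cluster), ",
    nrow(x$features$values), " patients\n",
    sep = ""
  )
  invisible(x)
}
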