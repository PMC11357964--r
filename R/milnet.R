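#' Initialise a one-hidden-layer multi-instance network
#'
#' The network maps a p-dimensional normalised feature vector to a
#' probability: a single hidden layer of rectified-linear units followed by
#' a logistic output, so every instance output lies in (0, 1). Weights are
#' drawn from zero-mean Gaussians scaled by fan-in; biases start at zero.
#'
#' @param input_dim Number of input features p.
#' @param hidden_dim Number of hidden units (default 50).
#' @param seed Integer seed; the same seed reproduces the weights exactly.
#' @return A `mil_network`: list with `W1` (p x hidden), `b1`, `w2`
#'   (hidden), `b2`, `input_dim`, `hidden_dim`, `seed`.
#' @export
mil_network <- function(input_dim, hidden_dim = 50, seed = 1) {
  if (input_dim < 1 || hidden_dim < 1) {
    stop("`input_dim` and `hidden_dim` must be positive.", call. = FALSE)
  }
  input_dim <- as.integer(input_dim)
  hidden_dim <- as.integer(hidden_dim)
  withr::with_seed(as.integer(seed), {
    structure(
      list(
        W1 = matrix(
          stats::rnorm(input_dim * hidden_dim, 0, sqrt(2 / input_dim)),
          input_dim, hidden_dim
        ),
        b1 = rep(0, hidden_dim),
        w2 = stats::rnorm(hidden_dim, 0, sqrt(1 / hidden_dim)),
        b2 = 0,
        input_dim = input_dim,
        hidden_dim = hidden_dim,
        seed = as.integer(seed)
      ),
      class = "mil_network"
    )
  })
}

# Forward pass for a matrix of instances (rows). Returns activations needed
# for backpropagation: pre-activation A, hidden H = relu(A), output o.
forward_instances <- function(net, X) {
  A <- sweep(X %*% net$W1, 2, net$b1, "+")
  H <- pmax(A, 0)
  z <- drop(H %*% net$w2) + net$b2
  list(A = A, H = H, z = z, o = stats::plogis(z))
}

#' Instance-level network outputs
#'
#' @param net A `mil_network`.
#' @param X Numeric matrix of normalised instances (one row each).
#' @return Numeric vector of outputs in (0, 1).
#' @export
predict_instances <- function(net, X) {
  forward_instances(net, as.matrix(X))$o
}

#' Predict a single bag
#'
#' The bag output is the maximum of its instances' network outputs
#' (max pooling), so it is invariant to instance order.
#'
#' @param net A `mil_network`.
#' @param instance_rows Integer row indices of the bag's instances.
#' @param features The `feature_matrix` the rows index into.
#' @return Bag prediction in (0, 1).
#' @export
predict_bag <- function(net, instance_rows, features) {
  if (length(instance_rows) == 0L) {
    stop("A bag must contain at least one instance.", call. = FALSE)
  }
  X <- features$values[instance_rows, , drop = FALSE]
  max(predict_instances(net, X))
}

#' Predict every bag of a dataset
#'
#' @param net A `mil_network`.
#' @param dataset A `bag_dataset`.
#' @return Numeric vector of bag predictions, aligned with `dataset$bags`.
#' @export
predict_bags <- function(net, dataset) {
  stopifnot(inherits(dataset, "bag_dataset"))
  o <- predict_instances(net, dataset$features$values)
  vapply(dataset$bags$instance_rows, function(r) max(o[r]), numeric(1))
}

#' Squared-error output error of one bag
#'
#' `E_i = (o_i - L_i)^2 / 2`, the per-bag error accumulated into the global
#' error each epoch and the uniform fallback wherever the calibration loss
#' is non-differentiable.
#'
#' @param o_i Bag prediction(s) in \[0, 1\].
#' @param L_i Bag label(s) in \[0, 1\].
#' @return Nonnegative error(s).
#' @export
bag_error <- function(o_i, L_i) {
  0.5 * (o_i - L_i)^2
}

mil_losses <- c("HL", "MSE", "MAE", "HUBER", "LOGCOSH")

# Numerically stable log(cosh(r))
log_cosh <- function(r) {
  a <- abs(r)
  a + log1p(exp(-2 * a)) - log(2)
}

clamp01 <- function(p, eps = 1e-12) pmin(1 - eps, pmax(eps, p))

# HL-style loss on frozen bins; degenerate bins (zero expected mass on
# either side) contribute their summed squared-error terms instead.
hl_loss_value <- function(p, y, Q) {
  p <- clamp01(p)
  bins <- hl_bin_index(p, Q)
  total <- 0
  for (q in seq_len(Q)) {
    idx <- which(bins == q)
    S <- sum(p[idx])
    O <- sum(y[idx])
    nq <- length(idx)
    if (S <= 0 || nq - S <= 0) {
      total <- total + sum(bag_error(p[idx], y[idx]))
    } else {
      total <- total + (O - S)^2 * (1 / S + 1 / (nq - S))
    }
  }
  total
}

# Bin membership (1..Q) per observation, by ascending prediction with stable
# ties, remainder spread over the first bins — matches bin_bags().
hl_bin_index <- function(p, Q) {
  n <- length(p)
  base <- n %/% Q
  extra <- n %% Q
  sizes <- rep(base, Q) + c(rep(1L, extra), rep(0L, Q - extra))
  bins <- integer(n)
  bins[order(p)] <- rep(seq_len(Q), times = sizes)
  bins
}

loss_value <- function(p, y, loss, Q = 10, huber_delta = 1) {
  r <- p - y
  switch(loss,
    MSE = sum(0.5 * r^2),
    MAE = sum(abs(r)),
    HUBER = sum(ifelse(abs(r) <= huber_delta,
      0.5 * r^2,
      huber_delta * abs(r) - 0.5 * huber_delta^2
    )),
    LOGCOSH = sum(log_cosh(r)),
    HL = hl_loss_value(p, y, Q),
    stop("Unknown loss `", loss, "`.", call. = FALSE)
  )
}

# dLoss/dprediction per bag; for HL the bin memberships are frozen at the
# current predictions (straight-through past the sort).
loss_grad_p <- function(p, y, loss, Q = 10, huber_delta = 1) {
  r <- p - y
  switch(loss,
    MSE = r,
    MAE = sign(r),
    HUBER = ifelse(abs(r) <= huber_delta, r, huber_delta * sign(r)),
    LOGCOSH = tanh(r),
    HL = {
      pc <- clamp01(p)
      bins <- hl_bin_index(pc, Q)
      g <- numeric(length(p))
      for (q in seq_len(Q)) {
        idx <- which(bins == q)
        S <- sum(pc[idx])
        O <- sum(y[idx])
        nq <- length(idx)
        if (S <= 0 || nq - S <= 0) {
          g[idx] <- pc[idx] - y[idx]
        } else {
          g[idx] <- 2 * (S - O) * (1 / S + 1 / (nq - S)) +
            (O - S)^2 * (1 / (nq - S)^2 - 1 / S^2)
        }
      }
      g
    },
    stop("Unknown loss `", loss, "`.", call. = FALSE)
  )
}

#' Total loss of a network on a bag dataset
#'
#' Sums the configured loss over all bags: the calibration (HL) loss
#' evaluates the grouped chi-square form on the bag predictions, and the
#' four regression baselines (MSE, MAE, Huber, log-cosh) sum their
#' per-bag terms.
#'
#' @param net A `mil_network`.
#' @param dataset A `bag_dataset`.
#' @param loss One of `"HL"`, `"MSE"`, `"MAE"`, `"HUBER"`, `"LOGCOSH"`
#'   (case-insensitive).
#' @param Q Calibration groups for the HL loss.
#' @param huber_delta Huber transition point.
#' @return Nonnegative total loss.
#' @export
dataset_loss <- function(net, dataset, loss = "HL", Q = 10, huber_delta = 1) {
  loss <- match.arg(toupper(loss), mil_losses)
  p <- predict_bags(net, dataset)
  loss_value(p, dataset$bags$label, loss, Q = Q, huber_delta = huber_delta)
}

# Analytic gradient of the dataset loss with respect to all weights.
# The gradient flows through the maximal instance of each bag only
# (subgradient of max pooling); HL bin memberships are frozen.
mil_gradient <- function(net, dataset, loss = "HL", Q = 10, huber_delta = 1) {
  loss <- match.arg(toupper(loss), mil_losses)
  X <- dataset$features$values
  fwd <- forward_instances(net, X)
  rows_list <- dataset$bags$instance_rows
  arg_rows <- vapply(rows_list, function(r) r[which.max(fwd$o[r])], integer(1))
  p <- fwd$o[arg_rows]
  g <- loss_grad_p(p, dataset$bags$label, loss, Q = Q, huber_delta = huber_delta)
  backprop_rows(net, X, fwd, arg_rows, g)
}

# Accumulate weight gradients for per-bag output gradients g attached to
# the given (argmax) instance rows.
backprop_rows <- function(net, X, fwd, arg_rows, g) {
  n <- nrow(X)
  dz_bag <- g * fwd$o[arg_rows] * (1 - fwd$o[arg_rows])
  u <- numeric(n)
  acc <- rowsum(dz_bag, group = arg_rows)
  u[as.integer(rownames(acc))] <- acc[, 1]
  used <- which(u != 0)
  Hu <- fwd$H[used, , drop = FALSE]
  D <- (u[used] %o% net$w2) * (fwd$A[used, , drop = FALSE] > 0)
  list(
    W1 = crossprod(X[used, , drop = FALSE], D),
    b1 = colSums(D),
    w2 = drop(crossprod(Hu, u[used])),
    b2 = sum(u[used])
  )
}

#' Train a multi-instance network by backpropagation
#'
#' Gradient descent on the configured loss. Each epoch computes every bag's
#' prediction (maximum instance output) and squared-error term; their sum is
#' the epoch's global error, and training stops early once it falls to or
#' below `global_error_threshold`. For the calibration (HL) loss, bin
#' memberships are frozen within each update step so the loss is piecewise
#' smooth. The default update mode applies one full-batch gradient step per
#' epoch; `update = "per_bag"` instead sweeps the bags in order, updating the
#' weights after each bag with that bag's share of the (epoch-frozen)
#' gradient.
#'
#' @param dataset A `bag_dataset` of training bags.
#' @param loss Loss name: `"HL"` (calibration loss) or one of the
#'   regression baselines `"MSE"`, `"MAE"`, `"HUBER"`, `"LOGCOSH"`.
#' @param hidden_dim Hidden units (default 50); ignored when `net` is given.
#' @param learning_rate Gradient-descent step size (default 0.001).
#' @param epochs Maximum number of epochs (default 200).
#' @param global_error_threshold Early-stop threshold on the summed per-bag
#'   squared error (default 0, which in practice disables early stopping).
#' @param Q Calibration groups for the HL loss and the per-epoch HL test.
#' @param huber_delta Huber transition point (used when `loss = "HUBER"`).
#' @param seed Seed for weight initialisation.
#' @param update `"batch"` (default) or `"per_bag"`.
#' @param net Optionally a pre-initialised `mil_network` to continue from.
#' @return A `mil_fit`: list with the trained `network`, a `history` tibble
#'   (`epoch`, `global_err`, `hl_statistic`, `hl_df`, `hl_p`), the loss
#'   name, `epochs_run`, and `converged` (whether the early stop fired).
#' @export
train_mil <- function(dataset,
                      loss = "HL",
                      hidden_dim = 50,
                      learning_rate = 0.001,
                      epochs = 200,
                      global_error_threshold = 0,
                      Q = 10,
                      huber_delta = 1,
                      seed = 1,
                      update = c("batch", "per_bag"),
                      net = NULL) {
  stopifnot(inherits(dataset, "bag_dataset"))
  loss <- match.arg(toupper(loss), mil_losses)
  update <- match.arg(update)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0.", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1.", call. = FALSE)
  if (nrow(dataset$bags) == 0L) stop("Empty bag dataset.", call. = FALSE)

  if (is.null(net)) {
    net <- mil_network(ncol(dataset$features$values), hidden_dim, seed = seed)
  }
  X <- dataset$features$values
  y <- dataset$bags$label
  rows_list <- dataset$bags$instance_rows
  n_bags <- length(y)
  hist <- vector("list", epochs)
  converged <- FALSE
  epochs_run <- 0L

  for (epoch in seq_len(epochs)) {
    fwd <- forward_instances(net, X)
    arg_rows <- vapply(
      rows_list, function(r) r[which.max(fwd$o[r])], integer(1)
    )
    p <- fwd$o[arg_rows]
    global_err <- sum(bag_error(p, y))
    if (!is.finite(global_err)) {
      stop("Training diverged (non-finite global error) at epoch ", epoch,
        call. = FALSE
      )
    }
    hl <- if (n_bags >= Q) hl_test(clamp01(p), y, Q) else NULL
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      global_err = global_err,
      hl_statistic = if (is.null(hl)) NA_real_ else hl$statistic,
      hl_df = if (is.null(hl)) NA_integer_ else hl$df,
      hl_p = if (is.null(hl)) NA_real_ else hl$p_value
    )
    epochs_run <- epoch

    # Bound each bag's output gradient to the scale the baseline losses can
    # produce (|dMAE/dp| = 1); the calibration loss is stiff in near-empty
    # boundary bins and unclipped steps overshoot at any fixed step size.
    g <- pmax(-1, pmin(1, loss_grad_p(p, y, loss, Q = Q, huber_delta = huber_delta)))
    if (update == "batch") {
      grad <- backprop_rows(net, X, fwd, arg_rows, g)
      net$W1 <- net$W1 - learning_rate * grad$W1
      net$b1 <- net$b1 - learning_rate * grad$b1
      net$w2 <- net$w2 - learning_rate * grad$w2
      net$b2 <- net$b2 - learning_rate * grad$b2
    } else {
      for (i in seq_len(n_bags)) {
        r <- rows_list[[i]]
        Xi <- X[r, , drop = FALSE]
        fi <- forward_instances(net, Xi)
        j <- which.max(fi$o)
        gr <- backprop_rows(net, Xi, fi, j, g[i])
        net$W1 <- net$W1 - learning_rate * gr$W1
        net$b1 <- net$b1 - learning_rate * gr$b1
        net$w2 <- net$w2 - learning_rate * gr$w2
        net$b2 <- net$b2 - learning_rate * gr$b2
      }
    }
    if (global_err <= global_error_threshold) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      network = net,
      history = dplyr::bind_rows(hist[seq_len(epochs_run)]),
      loss = loss,
      learning_rate = learning_rate,
      epochs = epochs,
      epochs_run = epochs_run,
      Q = Q,
      huber_delta = huber_delta,
      global_error_threshold = global_error_threshold,
      update = update,
      converged = converged,
      seed = as.integer(seed)
    ),
    class = "mil_fit"
  )
}

#' @export
print.mil_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<mil_fit> loss = %s, %d/%d epochs, final GlobalErr = %.4f, HL p = %.3g\n",
    x$loss, x$epochs_run, x$epochs, last$global_err, last$hl_p
  ))
  invisible(x)
}

#' Per-patient failure risk from a trained network
#'
#' Scores each patient as a singleton bag: the risk of treatment failure is
#' one minus the network's effectiveness output for that patient's feature
#' vector, transformed with the training normalisation.
#'
#' @param fit A `mil_fit` (or a bare `mil_network`).
#' @param patients Patient tibble with the clinical feature columns.
#' @param features The training `feature_matrix` carrying the normalisation.
#' @return Tibble of `patient_id` (if present), `effectiveness`, `risk`.
#' @export
predict_patient_risk <- function(fit, patients, features) {
  net <- if (inherits(fit, "mil_fit")) fit$network else fit
  stopifnot(inherits(net, "mil_network"))
  X <- apply_normalization(features, patients)
  o <- predict_instances(net, X)
  out <- tibble::tibble(effectiveness = o, risk = 1 - o)
  if ("patient_id" %in% names(patients)) {
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = patients$patient_id), out
    )
  }
  out
}

#' Select the Huber transition point by cross-validation
#'
#' K-fold cross-validation over bags: for each candidate delta the network is
#' trained on the complementary folds and scored by summed squared error on
#' the held-out fold; the delta with the lowest mean validation error wins
#' (ties to the smaller delta).
#'
#' @param dataset A `bag_dataset`.
#' @param grid Candidate deltas.
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and initialisation.
#' @param ... Passed on to [train_mil()] (e.g. `epochs`, `learning_rate`).
#' @return The selected delta (scalar), with attribute `cv` giving the
#'   per-delta mean validation errors.
#' @export
select_huber_delta <- function(dataset, grid = c(0.1, 0.5, 1.0), folds = 5,
                               seed = 1, ...) {
  n <- nrow(dataset$bags)
  fold_id <- withr::with_seed(
    as.integer(seed),
    sample(rep_len(seq_len(folds), n))
  )
  cv <- vapply(grid, function(delta) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- subset_bags(dataset, fold_id != f)
      va <- subset_bags(dataset, fold_id == f)
      fit <- train_mil(tr,
        loss = "HUBER", huber_delta = delta, seed = seed, ...
      )
      p <- predict_bags(fit$network, va)
      sum(bag_error(p, va$bags$label))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- grid[which.min(cv)]
  attr(best, "cv") <- stats::setNames(cv, grid)
  best
}

# Restrict a bag_dataset to a subset of bags (same feature matrix).
subset_bags <- function(dataset, keep) {
  out <- dataset
  out$bags <- dataset$bags[keep, , drop = FALSE]
  out
}
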