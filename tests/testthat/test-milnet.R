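test_that("network initialisation is seeded and validated", {
  n1 <- mil_network(5, seed = 7)
  n2 <- mil_network(5, seed = 7)
  expect_identical(n1, n2)
  expect_equal(n1$hidden_dim, 50) # default width
  expect_equal(dim(n1$W1), c(5, 50))
  n3 <- mil_network(5, seed = 8)
  expect_false(identical(n1$W1, n3$W1))
  expect_error(mil_network(0), "positive")
  expect_error(mil_network(5, 0), "positive")
})

test_that("bag prediction is the max over instances and permutation-invariant", {
  ds <- toy_bag_dataset(n_instances = 30, n_bags = 15, max_size = 6, seed = 2)
  net <- mil_network(5, 20, seed = 3)
  o <- predict_instances(net, ds$features$values)
  expect_true(all(o > 0 & o < 1))
  for (i in seq_len(nrow(ds$bags))) {
    rows <- ds$bags$instance_rows[[i]]
    # oracle: explicit per-instance forward pass, one at a time, then max
    one_at_a_time <- vapply(rows, function(r) {
      predict_instances(net, ds$features$values[r, , drop = FALSE])
    }, numeric(1))
    p <- predict_bag(net, rows, ds$features)
    expect_equal(p, max(one_at_a_time), tolerance = 1e-12)
    expect_equal(predict_bag(net, rev(rows), ds$features), p)
    shuffled <- rows[sample.int(length(rows))]
    expect_equal(predict_bag(net, shuffled, ds$features), p)
  }
  expect_equal(
    predict_bags(net, ds),
    vapply(ds$bags$instance_rows, predict_bag,
      net = net, features = ds$features, FUN.VALUE = numeric(1)
    )
  )
  expect_error(predict_bag(net, integer(0), ds$features), "at least one")
})

test_that("the per-bag output error is the half squared difference", {
  expect_equal(bag_error(0.7, 0.2), 0.125)
  expect_equal(bag_error(0.4, 0.4), 0)
  expect_equal(bag_error(0.2, 0.7), bag_error(0.7, 0.2)) # symmetric
})

test_that("dataset losses evaluate the five configured forms", {
  ds <- toy_bag_dataset(seed = 4)
  net <- mil_network(5, 10, seed = 5)
  p <- predict_bags(net, ds)
  # single worked bag: direct evaluation of each loss at (0.5, 0.3)
  r <- 0.5 - 0.3
  expect_equal(milcalib:::loss_value(0.5, 0.3, "MSE"), 0.02)
  expect_equal(milcalib:::loss_value(0.5, 0.3, "MAE"), 0.2)
  expect_equal(milcalib:::loss_value(0.5, 0.3, "HUBER", huber_delta = 1), 0.02)
  expect_equal(milcalib:::loss_value(0.5, 0.3, "LOGCOSH"), log(cosh(0.2)),
    tolerance = 1e-12
  )
  expect_equal(log(cosh(0.2)), 0.0199, tolerance = 1e-2)
  # predictions equal to labels: every loss vanishes
  ds0 <- ds
  ds0$bags$label <- p
  for (l in c("HL", "MSE", "MAE", "HUBER", "LOGCOSH")) {
    expect_equal(dataset_loss(net, ds0, loss = l, Q = 3), 0, tolerance = 1e-20)
  }
  # within delta the Huber loss is exactly its quadratic branch
  y <- ds$bags$label
  expect_equal(
    milcalib:::loss_value(p, y, "HUBER", huber_delta = max(abs(p - y)) + 0.1),
    milcalib:::loss_value(p, y, "MSE")
  )
  # outside delta it is the linear branch
  expect_equal(
    milcalib:::loss_value(0.9, 0.1, "HUBER", huber_delta = 0.5),
    0.5 * 0.8 - 0.5 * 0.25
  )
  expect_error(dataset_loss(net, ds, loss = "CAUCHY"))
})

test_that("analytic gradients match central finite differences", {
  ds <- toy_bag_dataset(n_instances = 12, n_bags = 8, max_size = 3, seed = 6)
  eps <- 1e-6
  for (loss in c("MSE", "HUBER", "LOGCOSH", "MAE")) {
    net <- mil_network(5, 6, seed = 11)
    ana <- milcalib:::mil_gradient(net, ds, loss = loss, huber_delta = 0.3)
    for (par in c("W1", "b1", "w2", "b2")) {
      fd <- array(0, dim = if (is.matrix(net[[par]])) dim(net[[par]]) else length(net[[par]]))
      for (i in seq_along(net[[par]])) {
        up <- net; up[[par]][i] <- up[[par]][i] + eps
        dn <- net; dn[[par]][i] <- dn[[par]][i] - eps
        fd[i] <- (dataset_loss(up, ds, loss, huber_delta = 0.3) -
          dataset_loss(dn, ds, loss, huber_delta = 0.3)) / (2 * eps)
      }
      expect_equal(as.numeric(ana[[par]]), as.numeric(fd),
        tolerance = 1e-5, ignore_attr = TRUE,
        label = paste(loss, par, "analytic"),
        expected.label = paste(loss, par, "finite-difference")
      )
    }
  }
})

test_that("training descends and honours the early-stop contract", {
  ds <- toy_bag_dataset(n_instances = 15, n_bags = 10, max_size = 4, seed = 20)
  fit <- train_mil(ds, loss = "MSE", epochs = 200, learning_rate = 0.01,
    Q = 3, seed = 21
  )
  expect_lt(fit$history$global_err[fit$epochs_run], fit$history$global_err[1])
  expect_equal(fit$epochs_run, 200) # threshold 0 never fires
  expect_false(fit$converged)
  # threshold above the initial error: one epoch, per the training loop
  init_err <- fit$history$global_err[1]
  fit1 <- train_mil(ds, loss = "MSE", epochs = 200, learning_rate = 0.01,
    Q = 3, seed = 21, global_error_threshold = init_err * 2
  )
  expect_equal(fit1$epochs_run, 1)
  expect_true(fit1$converged)
  # determinism under seed
  fit2 <- train_mil(ds, loss = "MSE", epochs = 50, Q = 3, seed = 21)
  fit3 <- train_mil(ds, loss = "MSE", epochs = 50, Q = 3, seed = 21)
  expect_identical(fit2$network, fit3$network)
  expect_identical(fit2$history, fit3$history)
})

test_that("per-bag and batch updates both descend on the HL loss", {
  ds <- toy_bag_dataset(n_instances = 20, n_bags = 12, max_size = 4, seed = 30)
  for (mode in c("batch", "per_bag")) {
    fit <- train_mil(ds, loss = "HL", epochs = 100, Q = 3, seed = 31,
      learning_rate = 0.01, update = mode
    )
    expect_lt(fit$history$global_err[fit$epochs_run], fit$history$global_err[1])
  }
})

test_that("size-one bags with squared error reduce to plain regression", {
  # oracle: an independent single-instance implementation (explicit loops)
  withr::with_seed(40, {
    n <- 12
    x <- matrix(runif(n * 5), n, 5)
    y <- runif(n)
  })
  ds <- structure(
    list(
      bags = tibble::tibble(
        bag_id = sprintf("B%02d", 1:n), cluster = 1L, size = 1L,
        instance_rows = as.list(1:n),
        instance_labels = as.list(y), label = y
      ),
      features = fm_from_matrix(x), labels = y,
      bags_per_cluster = n, seed = 40
    ),
    class = "bag_dataset"
  )
  lr <- 0.05
  fit <- train_mil(ds, loss = "MSE", epochs = 25, learning_rate = lr,
    Q = 3, seed = 41, hidden_dim = 4
  )
  # reference: plain gradient-descent regression on instances
  net <- mil_network(5, 4, seed = 41)
  for (ep in 1:25) {
    gW1 <- matrix(0, 5, 4); gb1 <- numeric(4); gw2 <- numeric(4); gb2 <- 0
    for (i in 1:n) {
      a <- drop(x[i, ] %*% net$W1) + net$b1
      h <- pmax(a, 0)
      o <- stats::plogis(sum(h * net$w2) + net$b2)
      dz <- (o - y[i]) * o * (1 - o)
      gw2 <- gw2 + dz * h
      gb2 <- gb2 + dz
      dh <- dz * net$w2 * (a > 0)
      gW1 <- gW1 + outer(x[i, ], dh)
      gb1 <- gb1 + dh
    }
    net$W1 <- net$W1 - lr * gW1
    net$b1 <- net$b1 - lr * gb1
    net$w2 <- net$w2 - lr * gw2
    net$b2 <- net$b2 - lr * gb2
  }
  expect_equal(fit$network$W1, net$W1, tolerance = 1e-10)
  expect_equal(fit$network$w2, net$w2, tolerance = 1e-10)
  expect_equal(fit$network$b2, net$b2, tolerance = 1e-10)
})

test_that("patient risks are complements of singleton predictions", {
  patients <- withr::with_seed(50, tibble::tibble(
    patient_id = sprintf("P%02d", 1:8),
    age = runif(8, 30, 80), gender = rbinom(8, 1, 0.5),
    mutation_abundance = runif(8), tp53 = rbinom(8, 1, 0.4),
    n_comutations = rpois(8, 3)
  ))
  f <- normalize_features(patients)
  net <- mil_network(5, 10, seed = 51)
  risks <- predict_patient_risk(net, patients, f)
  expect_true(all(risks$risk > 0 & risks$risk < 1))
  expect_equal(risks$risk, 1 - risks$effectiveness)
  # batch risks equal one-at-a-time risks
  single <- vapply(seq_len(8), function(i) {
    predict_patient_risk(net, patients[i, ], f)$risk
  }, numeric(1))
  expect_equal(risks$risk, single)
})

test_that("non-finite training errors are reported with their epoch", {
  ds <- toy_bag_dataset(seed = 60)
  ds$bags$label[1] <- NaN
  expect_error(
    train_mil(ds, loss = "MSE", epochs = 5, Q = 3, seed = 61),
    "epoch 1"
  )
})

test_that("cross-validated Huber delta comes from the candidate grid", {
  ds <- toy_bag_dataset(n_instances = 30, n_bags = 24, max_size = 4, seed = 70)
  delta <- select_huber_delta(ds, grid = c(0.1, 1), folds = 3, seed = 71,
    epochs = 10, Q = 3
  )
  expect_true(as.numeric(delta) %in% c(0.1, 1))
  expect_equal(length(attr(delta, "cv")), 2)
})
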