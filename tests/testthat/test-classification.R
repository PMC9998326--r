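# Balanced splits, the lambda grid, and penalized logistic regression
# checked against an independent full-batch optimizer.

test_that("prepare_datasets balances classes exactly for any imbalance", {
  labels <- c(rep("R", 300), rep("L", 100))
  sp <- prepare_datasets(labels, 0.2, seed = 1)
  expect_equal(sp$n_per_class, 100)
  expect_equal(length(sp$train_idx), 160)
  expect_equal(length(sp$test_idx), 40)
  # exact 50/50 in both partitions
  expect_equal(sum(labels[sp$train_idx] == "R"), 80)
  expect_equal(sum(labels[sp$test_idx] == "R"), 20)
  expect_equal(length(intersect(sp$train_idx, sp$test_idx)), 0)

  # determinism and seed sensitivity
  sp2 <- prepare_datasets(labels, 0.2, seed = 1)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- prepare_datasets(labels, 0.2, seed = 2)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  expect_warning(prepare_datasets(c(rep("R", 30), rep("L", 200))), "50")
  expect_error(suppressWarnings(prepare_datasets(c("R", "L"))), "2 trials")
})

test_that("the lambda grid is 30 log-spaced values over [1e-5/n, 1e5/n]", {
  for (n in c(1, 100, 517)) {
    g <- lambda_grid(n)
    expect_length(g, 30)
    expect_equal(g[1], 1e-5 / n)
    expect_equal(g[30], 1e5 / n)
    ratios <- g[-1] / g[-30]
    expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-12)
    expect_true(all(diff(g) > 0))
  }
})

test_that("a separable feature yields perfect training accuracy", {
  y <- rep(c("L", "R"), each = 20)
  x <- matrix(ifelse(y == "R", 1, -1) + 0, ncol = 1)
  clf <- fit_logistic_cv(x, y, penalty = "l1", seed = 3)
  expect_equal(evaluate_classifier(clf, x, y)$accuracy, 1)
})

test_that("coefficients at fixed lambda match a proximal-gradient oracle", {
  set.seed(21)
  n <- 20
  x <- matrix(rnorm(n * 3), n)
  y <- as.numeric(runif(n) < plogis(x[, 1] - 0.5 * x[, 2]))
  grid <- lambda_grid(n)
  for (alpha in c(1, 0)) {
    lam <- grid[15]
    ours <- premove:::penalized_logistic(x, y, alpha, grid, lam)
    oracle <- prox_logistic(x, y, lam, alpha)
    expect_lt(max(abs(c(ours$weights - oracle$weights,
                        ours$intercept - oracle$intercept))), 1e-4)
  }
})

test_that("a dominant l1 penalty shrinks every weight to zero", {
  set.seed(22)
  y <- rep(c("L", "R"), 20)
  x <- matrix(rnorm(40 * 4), 40)
  clf <- fit_logistic_cv(x, y, penalty = "l1", lambda = c(50, 100), seed = 1)
  expect_true(all(clf$weights == 0))
  ev <- evaluate_classifier(clf, x, y)
  expect_equal(ev$accuracy, 0.5)  # intercept-only on balanced labels
})

test_that("accuracy is symmetric under label flips", {
  set.seed(23)
  y <- rep(c("L", "R"), each = 15)
  x <- matrix(rnorm(30 * 2) + ifelse(y == "R", 1, 0), 30)
  clf <- fit_logistic_cv(x, y, penalty = "l2", seed = 1)
  flipped <- ifelse(y == "R", "L", "R")
  a1 <- evaluate_classifier(clf, x, y)$accuracy
  a2 <- evaluate_classifier(clf, x, flipped)$accuracy
  expect_equal(a1 + a2, 1)
})

test_that("the l1 active set shrinks along the lambda path", {
  set.seed(24)
  n <- 60
  x <- scale(matrix(rnorm(n * 8), n))
  y <- as.numeric(runif(n) < plogis(x[, 1] + 0.5 * x[, 3]))
  grid <- lambda_grid(n)
  fit <- premove:::penalized_logistic_path(x, y, alpha = 1, grid)
  nz <- vapply(sort(grid), function(s) {
    sum(as.numeric(stats::coef(fit, s = s))[-1] != 0)
  }, 0)
  expect_true(all(diff(nz) <= 0))  # ascending lambda -> fewer active features
})

test_that("CV lambda selection is invariant to feature scaling", {
  set.seed(25)
  y <- rep(c("L", "R"), each = 30)
  x <- matrix(rnorm(60 * 5) + ifelse(y == "R", 0.8, 0), 60)
  c1 <- fit_logistic_cv(x, y, penalty = "l1", seed = 4)
  c2 <- fit_logistic_cv(x * 10, y, penalty = "l1", seed = 4)
  expect_equal(c1$lambda, c2$lambda)
  expect_equal(predict(c1, x), predict(c2, x * 10), tolerance = 1e-8)
})

test_that("shuffled training labels give chance-level held-out accuracy", {
  ses <- std_session(2, n_trials = 140, seed = 101)
  ep <- prep_epochs(ses)
  split <- prepare_datasets(ep$labels, 0.2, seed = 6)
  train <- select_trials(ep, split$train_idx)
  test <- select_trials(ep, split$test_idx)
  fm <- suppressWarnings(fit_feature_ica(train, window_spec(-150, 150),
                                         M = 30, seed = 1))
  ftr <- ica_features(train, fm)
  fte <- ica_features(test, fm)
  true_train <- ep$labels[split$train_idx]
  accs <- vapply(1:10, function(s) {
    shuffled <- with_seed_labels(true_train, s)
    clf <- fit_logistic_cv(ftr, shuffled, seed = s)
    evaluate_classifier(clf, fte, ep$labels[split$test_idx])$accuracy
  }, 0)
  n_total <- 10 * length(split$test_idx)
  band <- chance_band(n_total)
  expect_gt(mean(accs), band[1])
  expect_lt(mean(accs), band[2])
})

test_that("the optional hinge-loss learner separates a shifted class", {
  set.seed(26)
  y <- rep(c("L", "R"), each = 30)
  x <- matrix(rnorm(60 * 3) + ifelse(y == "R", 1, 0), 60)
  clf <- fit_logistic_cv(x, y, penalty = "hinge", seed = 1)
  expect_equal(clf$penalty, "hinge")
  expect_gt(evaluate_classifier(clf, x, y)$accuracy, 0.8)
})
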