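# Balanced train/test preparation and regularized logistic regression with
# a cross-validated lambda grid.
#
# Class encoding: L -> -1, R -> +1; a positive linear score predicts a
# right-hand movement.

#' Balanced train/test split
#'
#' Randomly subsamples the majority class (without replacement) to the
#' minority count so the a-priori chance level is exactly 50%, then permutes
#' the trials of each class and splits them into train and test partitions.
#' Both partitions are exactly balanced.
#'
#' @param labels per-trial `"L"`/`"R"` labels.
#' @param test_frac fraction of each class held out for testing
#'   (default 0.2).
#' @param seed integer RNG seed; identical seeds give identical splits.
#' @return a `data_split`: list with integer `train_idx`, `test_idx`
#'   (indices into `labels`), and `seed`. A class with fewer than 50 trials
#'   raises a warning (too few to train and test reliably); fewer than 2 is
#'   an error.
#' @export
prepare_datasets <- function(labels, test_frac = 0.2, seed = 1) {
  labels <- as.character(labels)
  idx_l <- which(labels == "L"); idx_r <- which(labels == "R")
  n_min <- min(length(idx_l), length(idx_r))
  if (n_min < 2) stop("each class needs at least 2 trials")
  if (n_min < 50) {
    warning(sprintf("only %d trials in the rarer class; fewer than 50 is unreliable",
                    n_min))
  }
  with_seed(seed, {
    pick <- function(idx) sample(idx, n_min)   # subsample + permute
    l <- pick(idx_l); r <- pick(idx_r)
    n_test <- round(test_frac * n_min)
    split_one <- function(idx) {
      list(test = idx[seq_len(n_test)],
           train = idx[setdiff(seq_len(n_min), seq_len(n_test))])
    }
    sl <- split_one(l); sr <- split_one(r)
    structure(list(train_idx = sort(c(sl$train, sr$train)),
                   test_idx = sort(c(sl$test, sr$test)),
                   n_per_class = n_min, n_test_per_class = n_test,
                   seed = as.integer(seed)),
              class = "data_split")
  })
}

#' Regularization-coefficient grid
#'
#' 30 positive values, log-scaled (geometrically spaced) over
#' `[1e-5 / n_trials, 1e5 / n_trials]`, ascending.
#'
#' @param n_trials number of training trials.
#' @return numeric vector of 30 lambdas.
#' @export
lambda_grid <- function(n_trials) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  exp(seq(log(1e-5 / n_trials), log(1e5 / n_trials), length.out = 30))
}

label_to_y <- function(labels) ifelse(as.character(labels) == "R", 1, 0)

feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
}

# Stratified k-fold assignment; refolds with a fresh seed if any fold ends
# up single-class (only possible when a class has fewer members than k).
stratified_folds <- function(y, k, seed, max_tries = 5) {
  for (t in seq_len(max_tries)) {
    fold <- integer(length(y))
    with_seed(seed + t - 1, {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold == f])) == 2 && sum(fold != f & y == 0) > 0 &&
        sum(fold != f & y == 1) > 0
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build k folds with both classes present in every fold")
}

#' Regularized logistic regression with cross-validated lambda
#'
#' Standardizes the features (training statistics stored in the model), then
#' for every lambda on [lambda_grid()] computes the k-fold cross-validated
#' logistic loss, selects the loss-minimizing lambda (ties broken toward
#' the largest lambda, i.e. the most parsimonious model), and refits on all
#' training data at the selected value. The lasso (L1) penalty is the
#' default pairing for ICA-derived features and ridge (L2) for
#' spatiotemporal-PCA features.
#'
#' The convex objective `mean logistic loss + lambda * penalty` is minimized
#' with coordinate descent (glmnet); an optional `"hinge"` mode fits a
#' linear SVM (requires the e1071 package) for comparison.
#'
#' @param features a `feature_matrix` or plain trials x features matrix.
#' @param labels balanced `"L"`/`"R"` labels.
#' @param penalty `"l1"`, `"l2"`, or `"hinge"`; default chosen from the
#'   feature backend (l1 for ICA, l2 otherwise).
#' @param k number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param standardize standardize features before fitting (default TRUE).
#' @param lambda optional explicit grid (defaults to
#'   `lambda_grid(n_trials)`).
#' @return a `classifier_model`: `weights`, `intercept`, `penalty`,
#'   `lambda` (selected), `cv_curve` (lambda, CV loss, CV accuracy),
#'   standardization statistics, `cv_accuracy` at the selected lambda, and
#'   the feature backend id.
#' @export
fit_logistic_cv <- function(features, labels, penalty = NULL, k = 5,
                            seed = 1, standardize = TRUE, lambda = NULL) {
  x <- feature_values(features)
  backend <- if (inherits(features, "feature_matrix")) features$backend else "matrix"
  if (is.null(penalty)) penalty <- if (backend == "ica") "l1" else "l2"
  penalty <- match.arg(penalty, c("l1", "l2", "hinge"))
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- label_to_y(labels)
  if (length(unique(y)) != 2) stop("both classes must be present")
  n <- nrow(x)
  if (is.null(lambda)) lambda <- lambda_grid(n)
  lambda <- sort(lambda)

  centre <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (standardize) {
    s <- apply(x, 2, stats::sd); s[s < 1e-300] <- 1; s
  } else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")

  if (penalty == "hinge") {
    return(fit_hinge_cv(xs, y, labels, lambda, k, seed, centre, scale_, backend))
  }
  alpha <- if (penalty == "l1") 1 else 0
  p_orig <- ncol(xs)
  if (p_orig == 1) xs <- cbind(xs, 0)  # coordinate descent needs >= 2 columns
  fold <- stratified_folds(y, k, seed)
  loss_sum <- acc_sum <- numeric(length(lambda))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    fit <- penalized_logistic_path(xs[tr, , drop = FALSE], y[tr], alpha, lambda)
    p <- stats::predict(fit, xs[te, , drop = FALSE], type = "response",
                        s = rev(lambda), exact = FALSE)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    # columns of p follow rev(lambda); flip back to ascending order
    p <- p[, ncol(p):1, drop = FALSE]
    p[y[te] == 0, ] <- 1 - p[y[te] == 0, , drop = FALSE]  # prob. of true class
    loss_sum <- loss_sum - colSums(log(p))
    acc_sum <- acc_sum + colSums(p > 0.5)
  }
  cv_loss <- unname(loss_sum) / n
  cv_acc <- unname(acc_sum) / n
  best <- max(which(cv_loss <= min(cv_loss) + 1e-12))  # parsimony tie-break
  co <- penalized_logistic(xs, y, alpha, lambda, lambda[best])
  structure(list(weights = co$weights[seq_len(p_orig)], intercept = co$intercept,
                 penalty = penalty, lambda = lambda[best],
                 cv_curve = data.frame(lambda = lambda, cv_loss = cv_loss,
                                       cv_accuracy = cv_acc),
                 cv_accuracy = cv_acc[best], center = centre, scale = scale_,
                 standardize = standardize, feature_backend = backend,
                 n_features = ncol(x), k = k, seed = as.integer(seed)),
            class = "classifier_model")
}

# Coordinate-descent fit of the penalized logistic path over the lambda
# grid (objective: mean logistic deviance + lambda * penalty, with
# lambda*|w|_1 for alpha = 1 and lambda/2*|w|_2^2 for alpha = 0; intercept
# unpenalized).
penalized_logistic_path <- function(x, y, alpha, lambda) {
  glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                 lambda = rev(sort(lambda)), standardize = FALSE,
                 thresh = 1e-10, maxit = 1e6)
}

# Coefficients of the penalized logistic fit at one fixed lambda (fitted
# along the full grid path for warm-start stability).
penalized_logistic <- function(x, y, alpha, lambda, s) {
  fit <- penalized_logistic_path(x, y, alpha, lambda)
  co <- as.numeric(stats::coef(fit, s = s, exact = FALSE))
  list(intercept = co[1], weights = co[-1])
}

# Linear SVM comparison learner: hinge loss, CV-accuracy lambda selection.
fit_hinge_cv <- function(xs, y, labels, lambda, k, seed, centre, scale_,
                         backend) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("penalty = 'hinge' requires the e1071 package")
  }
  n <- nrow(xs)
  fold <- stratified_folds(y, k, seed)
  acc <- sapply(lambda, function(lam) {
    cost <- 1 / (n * lam)
    correct <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- e1071::svm(xs[tr, , drop = FALSE], factor(y[tr]), kernel = "linear",
                      cost = cost, scale = FALSE)
      correct <- correct + sum(stats::predict(m, xs[!tr, , drop = FALSE]) ==
                                 factor(y[!tr], levels = levels(factor(y[tr]))))
    }
    correct / n
  })
  best <- max(which(acc >= max(acc) - 1e-12))
  m <- e1071::svm(xs, factor(y), kernel = "linear", cost = 1 / (n * lambda[best]),
                  scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # orient so a positive score predicts class "1" (right hand), checking
  # against the fitted model's own training predictions
  pred <- stats::predict(m, xs) == "1"
  score <- drop(xs %*% w) + b
  if (mean((score > 0) == pred) < 0.5) { w <- -w; b <- -b }
  structure(list(weights = as.numeric(w), intercept = b, penalty = "hinge",
                 lambda = lambda[best],
                 cv_curve = data.frame(lambda = lambda, cv_loss = NA_real_,
                                       cv_accuracy = acc),
                 cv_accuracy = acc[best], center = centre, scale = scale_,
                 standardize = TRUE, feature_backend = backend,
                 n_features = ncol(xs), k = k, seed = as.integer(seed)),
            class = "classifier_model")
}

#' Linear decision scores
#'
#' @param object a `classifier_model`.
#' @param features feature matrix compatible with the model.
#' @param ... unused.
#' @return numeric scores; positive predicts `"R"`, non-positive `"L"`.
#' @export
predict.classifier_model <- function(object, features, ...) {
  x <- feature_values(features)
  if (ncol(x) != object$n_features) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(x), object$n_features))
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(xs %*% object$weights) + object$intercept
}

#' Classification accuracy on labeled trials
#'
#' Predicted class is the sign of the linear score (positive = right hand);
#' accuracy is the fraction of correctly classified trials.
#'
#' @param model a `classifier_model`.
#' @param features feature matrix for the evaluation trials.
#' @param labels true `"L"`/`"R"` labels.
#' @return list with `accuracy`, `predictions` (character vector), and
#'   `scores`.
#' @export
evaluate_classifier <- function(model, features, labels) {
  scores <- predict(model, features)
  pred <- ifelse(scores > 0, "R", "L")
  list(accuracy = mean(pred == as.character(labels)), predictions = pred,
       scores = scores)
}

#' @exportS3Method base::print
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model> %s penalty, lambda = %.3g, %d features (%s), CV accuracy %.3f\n",
              x$penalty, x$lambda, x$n_features, x$feature_backend,
              x$cv_accuracy))
  invisible(x)
}
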