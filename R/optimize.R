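# Parameter-optimization procedures: time-window grid search, greedy channel
# selection with point-based ranking and group aggregation, and learning
# curves over calibration-trial counts.

#' Enumerate candidate classification windows
#'
#' For each window size `s`, positions start at `anchor_start` and shift by
#' `step` until the window end would pass `max_end`:
#' `[anchor_start + k*step, anchor_start + k*step + s]`. A 600 ms window
#' over -550..150 ms with 100 ms shifts yields exactly the two positions
#' (-550, 50) and (-450, 150).
#'
#' @param sizes window sizes in ms (default the full ladder 600..50).
#' @param step shift between positions, ms.
#' @param anchor_start first window start, ms relative to stimulus onset.
#' @param max_end latest admissible window end, ms.
#' @return a `window_grid`: list with the parameters, `windows` (list of
#'   [window_spec()]) and a summary `table` (start, end, size).
#' @export
enumerate_windows <- function(sizes = c(600, 500, 400, 300, 200, 150, 100, 50),
                              step = 100, anchor_start = -550, max_end = 150) {
  span <- max_end - anchor_start
  windows <- list()
  for (s in sizes) {
    if (s > span) {
      warning(sprintf("window size %g ms exceeds span %g ms; skipped", s, span))
      next
    }
    k <- 0
    while (anchor_start + k * step + s <= max_end) {
      windows[[length(windows) + 1]] <-
        window_spec(anchor_start + k * step, anchor_start + k * step + s)
      k <- k + 1
    }
  }
  tab <- data.frame(start = vapply(windows, `[[`, 0, "start_ms"),
                    end = vapply(windows, `[[`, 0, "end_ms"))
  tab$size <- tab$end - tab$start
  structure(list(sizes = sizes, step = step, anchor_start = anchor_start,
                 max_end = max_end, windows = windows, table = tab),
            class = "window_grid")
}

backend_fit <- function(train, window, backend, M, seed, ...) {
  switch(backend,
         ica = fit_feature_ica(train, window, M = M, seed = seed, ...),
         st_pca = fit_spatiotemporal_pca(train, window, M = M),
         stop("unknown backend: ", backend))
}

backend_features <- function(epochs, model) {
  if (inherits(model, "feature_ica_model")) ica_features(epochs, model)
  else st_features(epochs, model)
}

# One shuffled balanced 80/20 split -> test accuracy, fitting the feature
# model and classifier on the training partition only.
split_accuracy <- function(epochs, labels, window, backend, M, split_seed,
                           fit_seed = 1, ...) {
  split <- prepare_datasets(labels, 0.2, seed = split_seed)
  train <- select_trials(epochs, split$train_idx)
  test <- select_trials(epochs, split$test_idx)
  fm <- backend_fit(train, window, backend, M, fit_seed, ...)
  clf <- fit_logistic_cv(backend_features(train, fm), labels[split$train_idx],
                         seed = fit_seed)
  evaluate_classifier(clf, backend_features(test, fm),
                      labels[split$test_idx])$accuracy
}

#' Grid search for the optimal classification window
#'
#' Evaluates every window in the grid by the mean held-out accuracy over
#' `n_shuffles` independent balanced 80/20 splits (feature model and
#' classifier refitted per split on training data only). The same shuffle
#' seeds are shared across windows (paired comparison), which stabilizes the
#' argmax without biasing individual estimates.
#'
#' @param epochs an [eeg_epochs()].
#' @param labels per-trial labels.
#' @param grid a `window_grid` from [enumerate_windows()].
#' @param n_shuffles number of random splits per window (default 20).
#' @param backend `"ica"` or `"st_pca"`.
#' @param M number of components.
#' @param seed base RNG seed.
#' @param ... passed to the feature fitter (e.g. `max_iter` for the ICA
#'   backend, to bound cost in large grid searches).
#' @return list with `best` (the argmax [window_spec()]; earliest window on
#'   ties) and `map` (the grid table with a mean `accuracy` column).
#' @export
optimize_window <- function(epochs, labels, grid, n_shuffles = 20,
                            backend = "ica", M = 30, seed = 1, ...) {
  accs <- vapply(seq_along(grid$windows), function(w) {
    mean(vapply(seq_len(n_shuffles), function(s) {
      split_accuracy(epochs, labels, grid$windows[[w]], backend, M,
                     split_seed = seed + s, ...)
    }, 0))
  }, 0)
  map <- grid$table
  map$accuracy <- accs
  list(best = grid$windows[[which.max(accs)]], map = map,
       n_shuffles = n_shuffles, backend = backend)
}

# 5-fold CV accuracy (and CV loss, used to resolve accuracy ties) of the
# ICA-feature classifier on a candidate channel set. Fold seeds are shared
# across candidates, so comparisons are paired; `cv_repeats` averages the
# score over repeated fold assignments, which tightens candidate
# comparisons at the cost of proportional compute.
channel_set_score <- function(epochs, labels, channels, window, M, k, seed,
                              cv_repeats = 1, ...) {
  sub <- select_channels(epochs, channels)
  fm <- fit_feature_ica(sub, window, M = M, seed = seed, ...)
  f <- ica_features(sub, fm)
  one <- function(fold_seed) {
    clf <- fit_logistic_cv(f, labels, k = k, seed = fold_seed)
    c(accuracy = clf$cv_accuracy,
      loss = clf$cv_curve$cv_loss[match(clf$lambda, clf$cv_curve$lambda)])
  }
  reps <- vapply(seq_len(cv_repeats), function(r) one(seed + (r - 1) * 131),
                 c(accuracy = 0, loss = 0))
  rowMeans(reps)
}

#' Greedy forward channel selection
#'
#' Starting from the empty set, channels are added greedily: the candidate
#' maximizing the 5-fold cross-validated accuracy of the ICA-feature
#' classifier is appended. Channels are added one at a time until 5 are
#' selected, then in blocks of 3 until 30, then in blocks of 5 (each block
#' is built as nested single-channel greedy additions; accuracy is compared
#' between block endpoints, so the evaluated set sizes run 1, 2, 3, 4, 5,
#' 8, 11, ...). Cross-validated accuracy is quantized in steps of 1/n, so
#' candidates within one binomial standard error of the best accuracy are
#' treated as statistically indistinguishable and resolved by the
#' cross-validated logistic loss (the one-standard-error rule); only exact
#' remaining ties fall back to lexicographic channel name (logged). The
#' selection order defines the channel ranking.
#'
#' @param epochs an [eeg_epochs()] (training data).
#' @param labels per-trial labels.
#' @param window the classification window (default -150..150 ms).
#' @param M number of ICA components (capped per candidate set size).
#' @param k CV folds.
#' @param seed RNG seed shared across candidate evaluations.
#' @param max_channels stop after this many channels are selected
#'   (default: rank all channels); the returned ranking is then partial.
#' @param cv_repeats repeated cross-validation rounds averaged per
#'   candidate score (default 3); selection among near-tied candidates is
#'   noise-limited, and averaging over fold assignments tightens it.
#' @param ... passed to [fit_feature_ica()] (e.g. a reduced `max_iter`;
#'   candidate scoring tolerates a coarse ICA).
#' @return a `channel_ranking`: `order` (all channels, selection order),
#'   `points` (band rule), `eval_sizes` (set sizes at which accuracy was
#'   compared), `accuracy` (score at each block endpoint), `ties` (log).
#' @export
greedy_channel_selection <- function(epochs, labels,
                                     window = window_spec(-150, 150),
                                     M = 30, k = 5, seed = 1,
                                     max_channels = NULL, cv_repeats = 3,
                                     ...) {
  all_chans <- epochs$channels
  if (length(all_chans) < 2) stop("need at least 2 channels")
  n_target <- if (is.null(max_channels)) length(all_chans)
              else min(max_channels, length(all_chans))
  selected <- character(0)
  eval_sizes <- integer(0)
  block_acc <- numeric(0)
  ties <- character(0)
  while (length(selected) < n_target) {
    n <- length(selected)
    block <- if (n < 5) 1L else if (n < 30) 3L else 5L
    block <- min(block, n_target - n)
    for (b in seq_len(block)) {
      remaining <- setdiff(all_chans, selected)
      scores <- vapply(remaining, function(ch) {
        channel_set_score(epochs, labels, c(selected, ch), window, M, k, seed,
                          cv_repeats = cv_repeats, ...)
      }, c(accuracy = 0, loss = 0))
      best <- max(scores["accuracy", ])
      se <- sqrt(best * (1 - best) / length(labels))
      top <- scores["accuracy", ] >= best - se - 1e-12
      best_loss <- min(scores["loss", top])
      cands <- sort(remaining[top & scores["loss", ] <= best_loss + 1e-12])
      if (length(cands) > 1) {
        ties <- c(ties, sprintf("size %d: tie among [%s]; chose %s",
                                n + b, paste(cands, collapse = ", "), cands[1]))
      }
      selected <- c(selected, cands[1])
    }
    eval_sizes <- c(eval_sizes, length(selected))
    block_acc <- c(block_acc, channel_set_score(epochs, labels, selected,
                                                window, M, k, seed,
                                                cv_repeats = cv_repeats,
                                                ...)[["accuracy"]])
  }
  structure(list(order = selected, points = channel_points(selected),
                 eval_sizes = eval_sizes, accuracy = block_acc, ties = ties,
                 window = window, seed = as.integer(seed)),
            class = "channel_ranking")
}

#' Ranking points from selection order
#'
#' Band rule: ranks 1-5 get 5 points, 6-15 get 3, 16-30 get 2, 31-50 get 1,
#' beyond 50 get 0.
#'
#' @param order channel labels in selection (rank) order.
#' @return named integer vector of points per channel.
#' @export
channel_points <- function(order) {
  rank <- seq_along(order)
  pts <- ifelse(rank <= 5, 5L,
         ifelse(rank <= 15, 3L,
         ifelse(rank <= 30, 2L,
         ifelse(rank <= 50, 1L, 0L))))
  stats::setNames(pts, order)
}

#' Group-level channel ranking
#'
#' Sums per-subject ranking points per channel. A subject missing a channel
#' contributes the mean of the other subjects' points for that channel;
#' channels absent in every subject are excluded with a warning. Totals are
#' normalized to 0-100 with respect to the single best channel.
#'
#' @param per_subject_points list of named point vectors (one per subject),
#'   e.g. the `points` element of [greedy_channel_selection()] results.
#' @return list with `points` (imputed totals), `normalized` (0-100) and
#'   `order` (channels by decreasing score).
#' @export
aggregate_group_ranking <- function(per_subject_points) {
  stopifnot(length(per_subject_points) >= 1)
  chans <- unique(unlist(lapply(per_subject_points, names)))
  if (length(chans) == 0) {
    warning("no channel scored by any subject")
    return(list(points = numeric(0), normalized = numeric(0),
                order = character(0)))
  }
  totals <- vapply(chans, function(ch) {
    obs <- vapply(per_subject_points, function(p) {
      if (ch %in% names(p)) p[[ch]] else NA_real_
    }, 0)
    fill <- mean(obs, na.rm = TRUE)
    sum(ifelse(is.na(obs), fill, obs))
  }, 0)
  normalized <- 100 * totals / max(totals)
  ord <- order(-totals, chans)
  list(points = totals, normalized = normalized, order = chans[ord])
}

#' Accuracy as a function of training-set size
#'
#' For each training size n in `start, start + step, ...` per class (up to
#' the minority class count minus the holdout), fits the pipeline on n
#' randomly chosen trials per class and tests on `holdout_per_class` trials
#' per class; the shuffling of training and test sets is repeated
#' `n_shuffles` times and accuracies averaged. Training sets are nested
#' within a shuffle, so the curve reflects added data rather than resampling
#' noise.
#'
#' @param epochs an [eeg_epochs()].
#' @param labels per-trial labels.
#' @param window classification window.
#' @param start,step training-trials-per-class schedule (default 10, 20).
#' @param holdout_per_class held-out test trials per class (default 20).
#' @param n_shuffles repetitions (default 20).
#' @param backend,M feature backend settings.
#' @param seed base RNG seed.
#' @param ... passed to the feature fitter.
#' @return a `learning_curve`: data.frame `curve` (n_per_class,
#'   mean_accuracy, sd_accuracy) plus settings. Truncated with a warning if
#'   trials run short.
#' @export
learning_curve <- function(epochs, labels, window = window_spec(-150, 150),
                           start = 10, step = 20, holdout_per_class = 20,
                           n_shuffles = 20, backend = "ica", M = 30,
                           seed = 1, ...) {
  labels <- as.character(labels)
  n_min <- min(sum(labels == "L"), sum(labels == "R"))
  n_max <- n_min - holdout_per_class
  if (n_max < start) {
    stop(sprintf("need at least %d trials per class (have %d)",
                 start + holdout_per_class, n_min))
  }
  sizes <- seq(start, n_max, by = step)
  acc <- matrix(0, n_shuffles, length(sizes))
  for (s in seq_len(n_shuffles)) {
    perm <- with_seed(seed + s, list(
      L = sample(which(labels == "L")), R = sample(which(labels == "R"))))
    test_idx <- c(perm$L[seq_len(holdout_per_class)],
                  perm$R[seq_len(holdout_per_class)])
    test <- select_trials(epochs, test_idx)
    for (j in seq_along(sizes)) {
      n <- sizes[j]
      tr_idx <- c(perm$L[holdout_per_class + seq_len(n)],
                  perm$R[holdout_per_class + seq_len(n)])
      train <- select_trials(epochs, tr_idx)
      fm <- backend_fit(train, window, backend, M, seed, ...)
      clf <- fit_logistic_cv(backend_features(train, fm), labels[tr_idx],
                             seed = seed)
      acc[s, j] <- evaluate_classifier(clf, backend_features(test, fm),
                                       labels[test_idx])$accuracy
    }
  }
  structure(list(curve = data.frame(n_per_class = sizes,
                                    mean_accuracy = colMeans(acc),
                                    sd_accuracy = apply(acc, 2, stats::sd)),
                 n_shuffles = n_shuffles, holdout_per_class = holdout_per_class,
                 backend = backend, window = window),
            class = "learning_curve")
}
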