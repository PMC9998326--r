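# Causal real-time simulation: calibrate on the earliest trials, then
# classify every later trial in chronological order.

#' Simulated real-time classification
#'
#' Emulates deployment: the first `n_calib_per_class` occurrences of each
#' hand are used to calibrate the feature model (ICA backend) and
#' classifier; every trial after the last calibration trial is then
#' classified in chronological order, without reshuffling and without
#' rebalancing of the test stream. Trials of the already-complete class
#' that occur before the last calibration index are part of neither set.
#' All data-dependent operators are frozen at calibration, and features use
#' only samples inside the mode's window, so predictions are strictly
#' causal: in `"pre_visual"` mode no sample at or after stimulus onset is
#' read.
#'
#' @param epochs an [eeg_epochs()] in chronological trial order.
#' @param labels per-trial `"L"`/`"R"` labels (chronological).
#' @param mode `"pre_movement"` (window -150..150 ms) or `"pre_visual"`
#'   (window -150..0 ms).
#' @param n_calib_per_class calibration trials per class (default 100).
#' @param M number of ICA components.
#' @param seed RNG seed for the classifier's internal cross-validation.
#' @param min_test results with fewer test trials than this are flagged
#'   `excluded` (default 25).
#' @return a `realtime_result`: `predictions` (data.frame with trial index,
#'   label, prediction, score), overall `accuracy`, `balanced_accuracy`
#'   (mean of per-class accuracies), `n_calibration_trials`,
#'   `n_test_trials`, `mode`, `window`, `excluded` flag.
#' @export
simulate_realtime <- function(epochs, labels,
                              mode = c("pre_movement", "pre_visual"),
                              n_calib_per_class = 100, M = 30, seed = 1,
                              min_test = 25) {
  mode <- match.arg(mode)
  window <- if (mode == "pre_movement") {
    window_spec(-150, 150)
  } else {
    # pre-visual: up to but excluding stimulus onset — no sample at
    # t >= 0 is ever read
    window_spec(-150, max(epochs$times[epochs$times < 0]))
  }
  labels <- as.character(labels)
  for (cls in c("L", "R")) {
    n_cls <- sum(labels == cls)
    if (n_cls < n_calib_per_class) {
      stop(sprintf("class %s has only %d trials; %d needed for calibration",
                   cls, n_cls, n_calib_per_class))
    }
  }
  occ <- function(cls) which(labels == cls)[seq_len(n_calib_per_class)]
  calib_idx <- sort(c(occ("L"), occ("R")))
  last_calib <- max(calib_idx)
  test_idx <- seq_along(labels)[seq_along(labels) > last_calib]

  calib <- select_trials(epochs, calib_idx)
  fm <- fit_feature_ica(calib, window, M = M, seed = seed)
  clf <- fit_logistic_cv(ica_features(calib, fm), labels[calib_idx],
                         seed = seed)

  if (length(test_idx) > 0) {
    test <- select_trials(epochs, test_idx)
    ev <- evaluate_classifier(clf, ica_features(test, fm), labels[test_idx])
    pred <- data.frame(trial = test_idx, label = labels[test_idx],
                       prediction = ev$predictions, score = ev$scores)
    accuracy <- ev$accuracy
    per_class <- vapply(c("L", "R"), function(cls) {
      sel <- pred$label == cls
      if (any(sel)) mean(pred$prediction[sel] == cls) else NA_real_
    }, 0)
    balanced <- mean(per_class, na.rm = TRUE)
  } else {
    pred <- data.frame(trial = integer(0), label = character(0),
                       prediction = character(0), score = numeric(0))
    accuracy <- balanced <- NA_real_
  }
  structure(list(predictions = pred, accuracy = accuracy,
                 balanced_accuracy = balanced,
                 n_calibration_trials = length(calib_idx),
                 n_test_trials = length(test_idx), mode = mode,
                 window = window, excluded = length(test_idx) < min_test,
                 feature_model = fm, classifier = clf),
            class = "realtime_result")
}

#' @exportS3Method base::print
print.realtime_result <- function(x, ...) {
  cat(sprintf("<realtime_result> mode %s, %d calibration / %d test trials%s\n",
              x$mode, x$n_calibration_trials, x$n_test_trials,
              if (x$excluded) " [EXCLUDED: too few test trials]" else ""))
  if (is.finite(x$accuracy)) {
    cat(sprintf("  accuracy %.3f (balanced %.3f)\n", x$accuracy,
                x$balanced_accuracy))
  }
  invisible(x)
}
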