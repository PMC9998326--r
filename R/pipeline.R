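# End-to-end recommended pipeline: configuration, orchestration, model
# persistence.

#' Pipeline configuration
#'
#' Defaults reproduce the recommended settings: the 32-channel montage
#' referenced to CPz, a fixed classification window of -150..150 ms around
#' visual-stimulus onset, ICA features with 30 components, lasso-logistic
#' classification with 5-fold cross-validated lambda, and preprocessing at
#' 1 kHz (1 Hz high-pass, 45 Hz low-pass, pre-stimulus-only rejection and
#' ICA cleaning).
#'
#' @param montage list with `channels` and `reference` (default
#'   [default_montage()]).
#' @param window classification [window_spec()] (default -150..150 ms).
#' @param backend `"ica"` or `"st_pca"`.
#' @param M number of components (default 30; capped at channels - 1).
#' @param test_frac held-out fraction per class (default 0.2).
#' @param epoch_pre_s,epoch_post_s epoch extent around stimulus, s.
#' @param resample_to working sampling rate, Hz.
#' @param highpass,lowpass filter cutoffs, Hz (set `NULL` to skip).
#' @param z_thresh robust-z threshold for outlier rejection.
#' @param exclude_channels peripheral channels removed unconditionally.
#' @param clean run artifact-reduction ICA (default TRUE).
#' @param clean_n_components cleaning ICA dimensionality (default 50).
#' @param seed master seed for split, ICA and classifier randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(montage = default_montage(),
                            window = window_spec(-150, 150),
                            backend = c("ica", "st_pca"), M = 30,
                            test_frac = 0.2, epoch_pre_s = 2.5,
                            epoch_post_s = 2.5, resample_to = 1000,
                            highpass = 1, lowpass = 45, z_thresh = 3.5,
                            exclude_channels = character(0), clean = TRUE,
                            clean_n_components = 50, seed = 1) {
  backend <- match.arg(backend)
  structure(list(montage = montage, window = window, backend = backend,
                 M = M, test_frac = test_frac, epoch_pre_s = epoch_pre_s,
                 epoch_post_s = epoch_post_s, resample_to = resample_to,
                 highpass = highpass, lowpass = lowpass, z_thresh = z_thresh,
                 exclude_channels = exclude_channels, clean = clean,
                 clean_n_components = clean_n_components,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the recommended end-to-end pipeline
#'
#' Preprocesses a continuous recording (high-pass, epoching, resampling,
#' low-pass, pre-stimulus outlier rejection, re-referencing, baseline
#' correction, optional ICA cleaning), restricts to the configured montage,
#' draws a balanced 80/20 split, fits the feature model and classifier on
#' the training partition, and evaluates on the held-out partition.
#'
#' @param recording an [eeg_recording()], or a path to one saved with
#'   [write_recording()].
#' @param config a [pipeline_config()].
#' @return a `premove_report`: held-out `accuracy`, per-trial `predictions`,
#'   preprocessing `removed` summary, fitted `feature_model` and
#'   `classifier`, the `config` echo and all seeds — enough to reproduce
#'   the run.
#' @export
run_recommended <- function(recording, config = pipeline_config()) {
  if (is.character(recording)) recording <- read_recording(recording)
  stopifnot(inherits(recording, "eeg_recording"))
  unknown <- setdiff(c(config$montage$channels, config$montage$reference),
                     recording$channels)
  if (length(unknown) > 0) {
    stop("montage channel(s) not in recording: ", paste(unknown, collapse = ", "))
  }

  rec <- recording
  if (!is.null(config$highpass)) {
    rec <- stage("highpass", fir_filter(rec, "highpass", config$highpass))
  }
  ep <- stage("epoching",
              extract_epochs(rec, config$epoch_pre_s, config$epoch_post_s))
  if (!is.null(config$resample_to) && config$resample_to < ep$fs) {
    ep <- stage("resampling", resample_epochs(ep, config$resample_to))
  }
  if (!is.null(config$lowpass)) {
    ep <- stage("lowpass", fir_filter(ep, "lowpass", config$lowpass))
  }
  rej <- stage("rejection",
               reject_outliers(ep, config$z_thresh,
                               exclude_channels = config$exclude_channels))
  ep <- rej$epochs
  ep <- stage("rereference", rereference(ep, config$montage$reference))
  ep <- stage("baseline", baseline_correct(ep))
  removed_components <- integer(0)
  if (isTRUE(config$clean)) {
    cl <- stage("ica cleaning",
                clean_ica(ep, config$clean_n_components, seed = config$seed))
    ep <- cl$epochs
    removed_components <- cl$model$removed_component_indices
  }
  keep <- intersect(config$montage$channels, ep$channels)
  ep <- stage("montage", select_channels(ep, keep))

  split <- stage("split",
                 prepare_datasets(ep$labels, config$test_frac, config$seed))
  train <- select_trials(ep, split$train_idx)
  test <- select_trials(ep, split$test_idx)
  fm <- stage("features",
              backend_fit(train, config$window, config$backend, config$M,
                          config$seed))
  clf <- stage("classifier",
               fit_logistic_cv(backend_features(train, fm),
                               ep$labels[split$train_idx],
                               seed = config$seed))
  ev <- stage("evaluation",
              evaluate_classifier(clf, backend_features(test, fm),
                                  ep$labels[split$test_idx]))
  structure(list(
    accuracy = ev$accuracy,
    predictions = data.frame(trial = split$test_idx,
                             label = ep$labels[split$test_idx],
                             prediction = ev$predictions, score = ev$scores),
    n_train = length(split$train_idx), n_test = length(split$test_idx),
    removed = list(channels = rej$report$channels_removed,
                   trials = rej$report$trials_removed,
                   ica_components = removed_components),
    channels_used = keep, lambda = clf$lambda, penalty = clf$penalty,
    feature_model = fm, classifier = clf, config = config,
    seed = config$seed), class = "premove_report")
}

#' @exportS3Method base::print
print.premove_report <- function(x, ...) {
  cat(sprintf("<premove_report> held-out accuracy %.3f (%d train / %d test trials)\n",
              x$accuracy, x$n_train, x$n_test))
  cat(sprintf("  backend %s, window %s, lambda %.3g (%s), %d channels\n",
              x$config$backend, format(x$config$window), x$lambda, x$penalty,
              length(x$channels_used)))
  invisible(x)
}

#' Serialize a fitted model bundle
#'
#' Writes the feature model, classifier and configuration to a lossless
#' JSON container. [load_model()] restores an identical bundle: predictions
#' on a fixed test set reproduce bitwise.
#'
#' @param feature_model a `feature_ica_model` or `pca_basis`.
#' @param classifier a `classifier_model`.
#' @param config the [pipeline_config()] used (optional).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(feature_model, classifier, config = NULL, path) {
  payload <- jsonlite::serializeJSON(list(feature_model = feature_model,
                                          classifier = classifier,
                                          config = config), digits = NA)
  writeLines(jsonlite::toJSON(list(format = "premove-model", version = 1L,
                                   payload = as.character(payload)),
                              auto_unbox = TRUE), path)
  invisible(path)
}

#' Restore a model bundle written by [save_model()]
#'
#' @param path file path.
#' @return list with `feature_model`, `classifier`, `config`.
#' @export
load_model <- function(path) {
  wrapper <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop("not a readable model file: ",
                                               conditionMessage(e), call. = FALSE))
  if (!identical(wrapper$format, "premove-model")) {
    stop("not a premove model file")
  }
  if (!identical(as.integer(wrapper$version), 1L)) {
    stop(sprintf("unsupported model version %s", wrapper$version))
  }
  jsonlite::unserializeJSON(wrapper$payload)
}
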