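# Core containers: continuous recordings and stimulus-locked epochs.

#' Continuous EEG recording
#'
#' Container for a continuous multichannel recording in microvolts, with an
#' event table of visual-stimulus onsets and per-trial hand labels, and
#' optional bipolar EMG channels.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels (10-5 names for
#'   scalp channels).
#' @param events numeric vector of stimulus-onset times in seconds, strictly
#'   increasing. May be empty for resting data.
#' @param labels per-trial hand labels, `"L"`/`"R"`, same length as `events`
#'   (or `NULL` for unlabeled data).
#' @param emg optional list with `data` (channels x samples) and `channels`
#'   for bipolar EMG.
#' @param meta optional named list of free-form metadata.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, events = numeric(0),
                          labels = NULL, emg = NULL, meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channels)) stop("channels must match rows of data")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (length(events) > 1 && any(diff(events) <= 0)) {
    stop("event times must be strictly increasing")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(events)) stop("one label per event required")
    if (!all(labels %in% c("L", "R"))) stop("labels must be 'L' or 'R'")
  }
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 events = as.numeric(events), labels = labels,
                 emg = emg, meta = meta),
            class = "eeg_recording")
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              length(x$events)))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d L / %d R\n", sum(x$labels == "L"),
                sum(x$labels == "R")))
  }
  if (!is.null(x$emg)) cat(sprintf("  EMG: %s\n", paste(x$emg$channels, collapse = ", ")))
  invisible(x)
}

#' Stimulus-locked epoch set
#'
#' Trials x channels x time array time-locked to visual-stimulus onset
#' (t = 0 ms), with per-trial hand labels.
#'
#' @param data numeric 3-D array, trials x channels x time, microvolts.
#' @param times numeric vector of sample times in ms relative to stimulus
#'   onset; length must match `dim(data)[3]`.
#' @param fs sampling rate in Hz.
#' @param channels channel labels matching `dim(data)[2]`.
#' @param labels per-trial `"L"`/`"R"` labels (or `NULL`).
#' @param reference reference description: `"none"`, `"average"` or a
#'   channel label.
#' @param log character vector of processing-history lines.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, fs, channels, labels = NULL,
                       reference = "none", log = character(0)) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels)) stop("channel dimension mismatch")
  if (dim(data)[3] != length(times)) stop("time dimension mismatch")
  if (!is.null(labels) && length(labels) != dim(data)[1]) {
    stop("one label per trial required")
  }
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, times = as.numeric(times), fs = fs,
                 channels = channels,
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 reference = reference, log = log),
            class = "eeg_epochs")
}

#' @exportS3Method base::print
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms, ref: %s\n",
              d[1], d[2], d[3], x$fs, min(x$times), max(x$times), x$reference))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

# Index of samples whose time (ms) lies in [start, end]; errors if the
# window is not fully covered by the epoch.
window_samples <- function(epochs, window) {
  idx <- which(epochs$times >= window$start_ms & epochs$times <= window$end_ms)
  if (length(idx) == 0L || window$start_ms < min(epochs$times) ||
      window$end_ms > max(epochs$times)) {
    stop(sprintf("window [%g, %g] ms outside epoch times [%g, %g] ms",
                 window$start_ms, window$end_ms, min(epochs$times),
                 max(epochs$times)))
  }
  idx
}

#' Select a subset of channels from an epoch set
#'
#' @param epochs an `eeg_epochs` object.
#' @param channels labels to keep, in the requested order.
#' @return the reduced `eeg_epochs`.
#' @export
select_channels <- function(epochs, channels) {
  missing <- setdiff(channels, epochs$channels)
  if (length(missing) > 0) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(channels, epochs$channels)
  eeg_epochs(epochs$data[, idx, , drop = FALSE], epochs$times, epochs$fs,
             channels, epochs$labels, epochs$reference,
             c(epochs$log, sprintf("select %d channels", length(channels))))
}

#' Select a subset of trials from an epoch set
#'
#' @param epochs an `eeg_epochs` object.
#' @param idx integer trial indices to keep.
#' @return the reduced `eeg_epochs`.
#' @export
select_trials <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$fs,
             epochs$channels,
             if (is.null(epochs$labels)) NULL else epochs$labels[idx],
             epochs$reference, epochs$log)
}

#' Time window relative to stimulus onset
#'
#' @param start_ms,end_ms window edges in ms relative to visual-stimulus
#'   onset; `start_ms < end_ms`.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(start_ms, end_ms) {
  if (!(start_ms < end_ms)) stop("window start must precede end")
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "window_spec")
}

#' @exportS3Method base::print
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %g to %g ms\n", x$start_ms, x$end_ms))
  invisible(x)
}

#' @exportS3Method base::format
format.window_spec <- function(x, ...) sprintf("[%g, %g] ms", x$start_ms, x$end_ms)
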