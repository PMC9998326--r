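# Preprocessing: zero-phase FIR filtering, epoching, resampling,
# pre-stimulus-only artifact rejection and ICA cleaning, EMG onset detection.
#
# Every data-driven cleaning decision is made from pre-stimulus samples only,
# so that task-period activity and artifacts cannot leak into the features
# through the cleaning path.

# Linear-phase FIR kernel by Hamming-windowed sinc design. The low-pass
# kernel is normalized to exactly unit DC gain; the high-pass is its
# spectral inversion, giving an exactly zero DC response. `order` is the
# filter order (taps = order + 1); odd orders are rounded up so the group
# delay is an integer number of samples.
fir_kernel <- function(kind, cutoff, fs, order) {
  if (order %% 2 == 1) order <- order + 1
  m <- order / 2
  n <- -m:m
  fc <- cutoff / fs
  h <- 2 * fc * sinc_fn(2 * fc * n)
  h <- h * (0.54 + 0.46 * cos(pi * n / m))  # Hamming window, centred
  h <- h / sum(h)
  if (kind == "highpass") {
    h <- -h
    h[m + 1] <- h[m + 1] + 1
  }
  h
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase application: forward convolution with a symmetric linear-phase
# kernel, then removal of the integer group delay. Edges are zero-padded, so
# the first/last order/2 samples are attenuated toward zero.
apply_fir <- function(x, h) {
  d <- (length(h) - 1) / 2
  n <- length(x)
  nfft <- stats::nextn(n + length(h) - 1, 2)  # pad: keeps the FFT fast
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[(d + 1):(d + n)]
}

#' Zero-phase FIR filtering
#'
#' Applies a Hamming-windowed-sinc FIR filter (high- or low-pass) to a
#' continuous recording or an epoch set, channel by channel. The kernel is
#' linear-phase and applied forward with group-delay compensation, i.e. the
#' output is zero-phase. Edges are zero-padded; the outermost `order/2`
#' samples taper toward zero.
#'
#' The default order scales with the sampling rate: one second of taps for
#' high-pass kernels and 0.1 s for low-pass kernels, which preserves the
#' transition-band behaviour of a 5000-tap 1 Hz high-pass and a 500-tap
#' 45 Hz low-pass at 5 kHz across sampling rates.
#'
#' @param x an [eeg_recording()] or [eeg_epochs()].
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff -6 dB cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (number of taps minus one); default scales
#'   with `fs` as described above. Must be >= 2.
#' @return the filtered object, same class and dimensions.
#' @export
fir_filter <- function(x, kind = c("highpass", "lowpass"), cutoff,
                       order = NULL) {
  kind <- match.arg(kind)
  fs <- x$fs
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (is.null(order)) {
    order <- round(fs * if (kind == "highpass") 1.0 else 0.1)
  }
  if (order < 2) stop("order must be >= 2")
  h <- fir_kernel(kind, cutoff, fs, order)
  if (inherits(x, "eeg_recording")) {
    x$data <- t(apply(x$data, 1, apply_fir, h = h))
    rownames(x$data) <- x$channels
  } else if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    for (i in seq_len(d[1])) {
      x$data[i, , ] <- t(apply(matrix(x$data[i, , ], nrow = d[2]),
                               1, apply_fir, h = h))
    }
    x$log <- c(x$log, sprintf("%s FIR %g Hz order %d", kind, cutoff, order))
  } else stop("x must be an eeg_recording or eeg_epochs")
  x
}

#' Extract stimulus-locked epochs
#'
#' Cuts the continuous recording into trials time-locked to each event, with
#' t = 0 at the stimulus sample. Events too close to the record edges are
#' dropped and listed in the `dropped` attribute and the processing log.
#'
#' @param recording an [eeg_recording()] with events.
#' @param pre_s,post_s seconds before/after stimulus onset to keep.
#' @return an [eeg_epochs()]; trials are ordered by event time.
#' @export
extract_epochs <- function(recording, pre_s = 2.5, post_s = 2.5) {
  fs <- recording$fs
  n <- ncol(recording$data)
  pre_n <- round(pre_s * fs); post_n <- round(post_s * fs)
  centre <- round(recording$events * fs) + 1L
  ok <- centre - pre_n >= 1L & centre + post_n <= n
  if (!any(ok)) stop("no event has enough surrounding samples")
  kept <- which(ok)
  data <- array(0, c(length(kept), nrow(recording$data), pre_n + post_n + 1L))
  for (i in seq_along(kept)) {
    idx <- (centre[kept[i]] - pre_n):(centre[kept[i]] + post_n)
    data[i, , ] <- recording$data[, idx]
  }
  dropped <- which(!ok)
  log <- sprintf("epoched %d trials (-%g..%g s); dropped %d at record edge",
                 length(kept), pre_s, post_s, length(dropped))
  ep <- eeg_epochs(data, times = (-pre_n:post_n) / fs * 1000, fs = fs,
                   channels = recording$channels,
                   labels = if (is.null(recording$labels)) NULL else recording$labels[kept],
                   reference = "none", log = log)
  attr(ep, "dropped") <- dropped
  ep
}

#' Resample epochs with anti-aliasing
#'
#' Rational-ratio resampling: the signal is upsampled by zero-insertion,
#' low-pass filtered with a zero-phase FIR anti-aliasing kernel (cutoff at
#' 0.4 of the lower of the two rates), and decimated. The first sample (and
#' hence t = 0 for stimulus-centred epochs) is preserved exactly.
#'
#' @param epochs an [eeg_epochs()].
#' @param target_fs target rate, Hz; must not exceed the current rate.
#' @return the resampled [eeg_epochs()].
#' @export
resample_epochs <- function(epochs, target_fs = 1000) {
  fs <- epochs$fs
  if (target_fs > fs) stop("target_fs must be <= current sampling rate")
  if (target_fs == fs) return(epochs)
  frac <- rational_ratio(target_fs / fs)
  p <- frac[1]; q <- frac[2]
  d <- dim(epochs$data)
  n_new <- floor((d[3] - 1) * p / q) + 1L
  fs_up <- fs * p
  h <- fir_kernel("lowpass", 0.4 * min(fs, target_fs), fs_up,
                  round(0.1 * fs_up / min(p, 10)))
  out <- array(0, c(d[1], d[2], n_new))
  for (i in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- epochs$data[i, c, ]
    up <- numeric(d[3] * p)
    up[seq(1, length(up), by = p)] <- x * p
    y <- apply_fir(up, h)
    out[i, c, ] <- y[seq(1, by = q, length.out = n_new)]
  }
  eeg_epochs(out, times = epochs$times[1] + (0:(n_new - 1)) * 1000 / target_fs,
             fs = target_fs, channels = epochs$channels, labels = epochs$labels,
             reference = epochs$reference,
             log = c(epochs$log, sprintf("resampled %g -> %g Hz", fs, target_fs)))
}

# Small continued-fraction rational approximation of a rate ratio.
rational_ratio <- function(r, tol = 1e-9, max_den = 10000) {
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < tol) return(c(p, q))
  }
  stop("cannot express resampling ratio as a small rational number")
}

#' Automated variance-based outlier rejection
#'
#' Automated surrogate for visual variance inspection: per-channel and
#' per-trial log-variances are computed on the pre-stimulus segment only
#' (t < 0), and entries whose robust z-score (median/MAD) exceeds
#' `z_thresh` in absolute value are removed. Because the MAD of a clean
#' sample can be arbitrarily small, an entry must additionally deviate from
#' the median variance by at least a factor `min_var_ratio` — a minimum
#' effect size that suppresses false alarms on clean data. Channels in
#' `exclude_channels` (e.g. peripheral electrodes affected by the reaching
#' movement) are removed unconditionally. Post-stimulus samples never
#' influence the decision.
#'
#' @param epochs an [eeg_epochs()] with >= 3 channels and >= 3 trials.
#' @param z_thresh robust z-score threshold (default 3.5).
#' @param min_var_ratio minimum variance ratio to the median for removal
#'   (default 2).
#' @param exclude_channels labels removed unconditionally.
#' @return list with `epochs` (cleaned) and `report` (removed channels and
#'   trials with their scores).
#' @export
reject_outliers <- function(epochs, z_thresh = 3.5, min_var_ratio = 2,
                            exclude_channels = character(0)) {
  d <- dim(epochs$data)
  if (d[1] < 3 || d[2] < 3) stop("need >= 3 trials and >= 3 channels")
  pre <- epochs$times < 0
  robust_z <- function(v) (v - stats::median(v)) / max(stats::mad(v), 1e-12)
  flag <- function(v) {
    abs(robust_z(v)) > z_thresh & abs(v - stats::median(v)) > log(min_var_ratio)
  }

  logvar <- matrix(0, d[1], d[2])  # trials x channels
  for (i in seq_len(d[1])) {
    logvar[i, ] <- log(apply(matrix(epochs$data[i, , pre], nrow = d[2]),
                             1, stats::var) + 1e-300)
  }
  chan_score <- apply(logvar, 2, stats::median)
  chan_z <- robust_z(chan_score)
  bad_chan <- flag(chan_score) | epochs$channels %in% exclude_channels
  if (all(bad_chan)) stop("data quality: all channels flagged as outliers")

  trial_score <- apply(logvar[, !bad_chan, drop = FALSE], 1, stats::median)
  trial_z <- robust_z(trial_score)
  bad_trial <- flag(trial_score)
  if (all(bad_trial)) stop("data quality: all trials flagged as outliers")

  report <- list(
    channels_removed = epochs$channels[bad_chan],
    trials_removed = which(bad_trial),
    channel_z = stats::setNames(chan_z, epochs$channels),
    trial_z = trial_z, z_thresh = z_thresh,
    excluded_unconditionally = intersect(exclude_channels, epochs$channels))
  out <- eeg_epochs(epochs$data[!bad_trial, !bad_chan, , drop = FALSE],
                    epochs$times, epochs$fs, epochs$channels[!bad_chan],
                    if (is.null(epochs$labels)) NULL else epochs$labels[!bad_trial],
                    epochs$reference,
                    c(epochs$log,
                      sprintf("rejected %d channels, %d trials (pre-stimulus robust z > %g)",
                              sum(bad_chan), sum(bad_trial), z_thresh)))
  list(epochs = out, report = report)
}

#' Re-reference epochs
#'
#' `"average"` subtracts the instantaneous mean across channels from every
#' channel; a channel label subtracts that channel's signal and removes the
#' channel from the data matrix.
#'
#' @param epochs an [eeg_epochs()].
#' @param mode `"average"` or a channel label (e.g. `"CPz"`).
#' @return the re-referenced [eeg_epochs()].
#' @export
rereference <- function(epochs, mode = "average") {
  d <- dim(epochs$data)
  if (identical(mode, "average")) {
    for (i in seq_len(d[1])) {
      slab <- matrix(epochs$data[i, , ], nrow = d[2])
      epochs$data[i, , ] <- sweep(slab, 2, colMeans(slab))
    }
    epochs$reference <- "average"
    epochs$log <- c(epochs$log, "re-referenced to channel average")
    epochs
  } else {
    ri <- match(mode, epochs$channels)
    if (is.na(ri)) stop("reference channel not present: ", mode)
    keep <- setdiff(seq_len(d[2]), ri)
    out <- epochs$data[, keep, , drop = FALSE]
    for (i in seq_len(d[1])) {
      ref <- epochs$data[i, ri, ]
      out[i, , ] <- sweep(matrix(out[i, , ], nrow = length(keep)), 2, ref)
    }
    eeg_epochs(out, epochs$times, epochs$fs, epochs$channels[keep],
               epochs$labels, reference = mode,
               log = c(epochs$log, paste("re-referenced to", mode)))
  }
}

#' Baseline correction from the pre-stimulus segment
#'
#' Subtracts, per trial and channel, the mean over the entire pre-stimulus
#' segment (t < 0).
#'
#' @param epochs an [eeg_epochs()].
#' @return the baseline-corrected [eeg_epochs()].
#' @export
baseline_correct <- function(epochs) {
  pre <- epochs$times < 0
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    base <- rowMeans(matrix(epochs$data[i, , pre], nrow = d[2]))
    epochs$data[i, , ] <- matrix(epochs$data[i, , ], nrow = d[2]) - base
  }
  epochs$log <- c(epochs$log, "baseline-corrected (pre-stimulus mean)")
  epochs
}

#' Artifact-reduction ICA fitted on pre-stimulus data
#'
#' Compresses the channel data to `n_components` dimensions, runs fixed-point
#' ICA (symmetric orthogonalization, Gaussian contrast) on the concatenated
#' pre-stimulus segments, and reconstructs the full epochs with the selected
#' components removed. The unmixing model is estimated from pre-stimulus
#' samples only; the identical transform is then applied to the entire
#' epoch, so cleaning is causal with respect to the stimulus.
#'
#' With `remove = "auto_ocular"`, components are flagged whose channel-space
#' mixing column loads maximally on the most anterior channel pair (AFp1 and
#' AFp2 when present) and whose pre-stimulus time course has excess kurtosis
#' above `kurt_thresh` (blinks are strongly super-Gaussian).
#'
#' @param epochs an [eeg_epochs()].
#' @param n_components number of ICA components (capped at channels - 1).
#' @param remove integer component indices, `"auto_ocular"`, or an empty
#'   vector to remove nothing (the data are then only projected onto the
#'   retained subspace).
#' @param kurt_thresh excess-kurtosis threshold for auto-ocular flagging.
#' @param seed,tol,max_iter,n_restarts ICA settings.
#' @return list with `epochs` (cleaned) and `model` (compression, demixing,
#'   mixing, removed component indices, per-component kurtosis).
#' @export
clean_ica <- function(epochs, n_components = 50, remove = "auto_ocular",
                      kurt_thresh = 5, seed = 1, tol = 1e-4, max_iter = 200,
                      n_restarts = 1) {
  d <- dim(epochs$data)
  pre <- epochs$times < 0
  M <- min(n_components, d[2] - 1L)
  # channels x (trials * pre-samples) fitting matrix
  Xfit <- matrix(aperm(epochs$data[, , pre, drop = FALSE], c(2, 1, 3)), d[2])
  wh <- pca_whiten(Xfit, M)
  M <- wh$M
  ica <- fastica_symm(wh$K %*% (Xfit - wh$mean), contrast = "gauss",
                      tol = tol, max_iter = max_iter, seed = seed,
                      n_restarts = n_restarts)
  demix <- ica$W %*% wh$K                 # components x channels
  mixing <- wh$K_inv %*% t(ica$W)         # channels x components
  S_fit <- demix %*% (Xfit - wh$mean)
  kurt <- apply(S_fit, 1, excess_kurtosis)

  if (identical(remove, "auto_ocular")) {
    pos <- channel_positions(epochs$channels)
    if (all(c("AFp1", "AFp2") %in% epochs$channels)) {
      anterior <- match(c("AFp1", "AFp2"), epochs$channels)
    } else {
      ord <- order(-pos$y, abs(pos$x), na.last = TRUE)
      anterior <- ord[1:2]
    }
    load_max <- apply(abs(mixing), 2, which.max)
    remove <- which(load_max %in% anterior & kurt > kurt_thresh)
  }
  remove <- as.integer(remove)

  keep <- setdiff(seq_len(M), remove)
  out <- epochs
  for (i in seq_len(d[1])) {
    Xi <- matrix(epochs$data[i, , ], nrow = d[2]) - wh$mean
    Si <- demix %*% Xi
    out$data[i, , ] <- mixing[, keep, drop = FALSE] %*%
      Si[keep, , drop = FALSE] + wh$mean
  }
  out$log <- c(out$log, sprintf("ICA cleaning: %d components, removed [%s]",
                                M, paste(remove, collapse = ", ")))
  model <- list(compression = wh$K, mean = wh$mean, demixing = demix,
                mixing = mixing, removed_component_indices = remove,
                kurtosis = kurt, n_components = M, channels = epochs$channels)
  class(model) <- "cleaning_ica_model"
  list(epochs = out, model = model)
}

#' EMG movement-onset detection
#'
#' Builds an EMG envelope (20 Hz high-pass, rectification, 10 Hz low-pass)
#' and returns the first post-stimulus time at which the envelope exceeds
#' half of its post-stimulus maximum.
#'
#' @param emg numeric vector, one trial's EMG segment, microvolts.
#' @param fs sampling rate, Hz.
#' @param stim_time stimulus time in seconds relative to the start of the
#'   segment.
#' @param min_amplitude envelope maxima below this (microvolts) are treated
#'   as "no movement".
#' @return onset in ms after the stimulus, or `NA_real_` if no movement was
#'   detected.
#' @export
detect_movement_onset <- function(emg, fs, stim_time, min_amplitude = 1) {
  h_hp <- fir_kernel("highpass", 20, fs, round(0.1 * fs))
  h_lp <- fir_kernel("lowpass", 10, fs, round(0.1 * fs))
  env <- apply_fir(abs(apply_fir(emg, h_hp)), h_lp)
  start <- round(stim_time * fs) + 1L
  if (start >= length(env)) stop("EMG segment must extend beyond the stimulus")
  post <- env[start:length(env)]
  peak <- max(post)
  if (!is.finite(peak) || peak < min_amplitude) return(NA_real_)
  onset <- which(post > 0.5 * peak)[1]
  (onset - 1) / fs * 1000
}
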