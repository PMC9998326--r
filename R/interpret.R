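# Neurophysiological read-outs: classifier topography, Morlet
# time-frequency class contrasts, and minimum-norm source projection.

#' Classifier-relevant scalp topography
#'
#' Maps the classifier's weights on the M component-mean features (after
#' undoing feature standardization) back to channel space through the ICA
#' mixing operator and the PCA decompression operator. The result is the
#' scalp distribution of the brain signal whose mean over the window is
#' most relevant for the left/right decision; its scale is arbitrary and the
#' sign is fixed so the largest-|value| left-hemisphere channel is positive
#' (evidence for an upcoming right-hand movement).
#'
#' `pattern = "forward"` uses the mixing/decompression mapping directly
#' (on whitened training data this equals the activation pattern);
#' `pattern = "covariance"` multiplies the channel-space discriminant by the
#' channel covariance of the training window instead.
#'
#' @param feature_model a `feature_ica_model`.
#' @param classifier a `classifier_model` trained on that model's
#'   mean/variance features.
#' @param pattern `"forward"` (default) or `"covariance"`.
#' @param chan_cov channel covariance matrix (required for
#'   `pattern = "covariance"`).
#' @return a `topography`: named per-channel `values`, `channels`, and the
#'   sign convention.
#' @export
classifier_topography <- function(feature_model, classifier,
                                  pattern = c("forward", "covariance"),
                                  chan_cov = NULL) {
  pattern <- match.arg(pattern)
  M <- feature_model$M
  if (!identical(classifier$feature_backend, "ica") ||
      classifier$n_features != 2 * M) {
    stop("classifier was not trained on this feature model's mean/variance features")
  }
  w_mean <- classifier$weights[seq_len(M)] / classifier$scale[seq_len(M)]
  if (pattern == "forward") {
    nu <- drop(feature_model$decompression %*% (feature_model$A %*% w_mean))
  } else {
    if (is.null(chan_cov)) stop("pattern = 'covariance' needs chan_cov")
    w_chan <- drop(t(feature_model$W %*% feature_model$compression) %*% w_mean)
    nu <- drop(chan_cov %*% w_chan)
  }
  names(nu) <- feature_model$channels
  pos <- channel_positions(feature_model$channels)
  left <- which(!is.na(pos$x) & pos$x < 0)
  if (length(left) > 0) {
    peak <- left[which.max(abs(nu[left]))]
    if (nu[peak] < 0) nu <- -nu
  }
  structure(list(values = nu, channels = feature_model$channels,
                 sign_convention = "positive = evidence for right-hand choice"),
            class = "topography")
}

# Complex Morlet wavelet power for one time series via FFT convolution,
# centred ("same") alignment. Returns power and the number of edge samples
# without full wavelet support.
morlet_power <- function(x, fs, freq, cycles) {
  sigma_t <- cycles / (2 * pi * freq)
  half <- floor(3 * sigma_t * fs)
  tt <- (-half:half) / fs
  w <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sum(abs(w))
  n <- length(x)
  L <- n + length(w) - 1
  nfft <- stats::nextn(L, 2)
  conv <- stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(w, numeric(nfft - length(w)))),
                     inverse = TRUE) / nfft
  centre <- conv[(half + 1):(half + n)]
  list(power = Mod(centre)^2, edge = half)
}

#' Normalized time-frequency class contrast
#'
#' Morlet-wavelet power (width `cycles` cycles) is computed per frequency
#' for every trial of each class, averaged over trials and over the listed
#' channels, and combined into the normalized difference
#' `(X1 - X2) / (X1 + X2)` with `X1` the right-hand and `X2` the left-hand
#' power. Values lie in \[-1, 1\]; samples without full wavelet support at
#' the epoch edges are `NA`.
#'
#' @param epochs_right,epochs_left [eeg_epochs()] for right-/left-hand
#'   trials; same channels and rate.
#' @param channels channel labels to average over (e.g. one hemisphere's
#'   sensorimotor set).
#' @param f_lo,f_hi frequency range, Hz (default 2-40; must stay below
#'   Nyquist).
#' @param f_step frequency resolution, Hz.
#' @param t_window c(start, end) ms of the output map (default -150..150).
#' @param cycles Morlet width (default 7).
#' @return a `tf_map`: `values` (freqs x times), `freqs`, `times`,
#'   `channels`.
#' @export
tf_difference <- function(epochs_right, epochs_left, channels, f_lo = 2,
                          f_hi = 40, f_step = 1, t_window = c(-150, 150),
                          cycles = 7) {
  if (!identical(epochs_right$channels, epochs_left$channels) ||
      !isTRUE(all.equal(epochs_right$fs, epochs_left$fs))) {
    stop("epoch sets must share channels and sampling rate")
  }
  fs <- epochs_right$fs
  if (f_hi >= fs / 2) stop("f_hi must be below the Nyquist frequency")
  missing <- setdiff(channels, epochs_right$channels)
  if (length(missing) > 0) {
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  }
  freqs <- seq(f_lo, f_hi, by = f_step)
  keep <- epochs_right$times >= t_window[1] & epochs_right$times <= t_window[2]
  times <- epochs_right$times[keep]

  class_power <- function(epochs) {
    ci <- match(channels, epochs$channels)
    nt <- dim(epochs$data)[1]
    out <- matrix(0, length(freqs), sum(keep))
    for (fi in seq_along(freqs)) {
      acc <- numeric(length(epochs$times))
      edge <- 0
      for (i in seq_len(nt)) for (c in ci) {
        mp <- morlet_power(epochs$data[i, c, ], fs, freqs[fi], cycles)
        acc <- acc + mp$power
        edge <- mp$edge
      }
      p <- acc / (nt * length(ci))
      n <- length(p)
      if (edge > 0) {
        p[seq_len(min(edge, n))] <- NA_real_
        p[seq.int(max(1, n - edge + 1), n)] <- NA_real_
      }
      out[fi, ] <- p[keep]
    }
    out
  }
  x1 <- class_power(epochs_right)
  x2 <- class_power(epochs_left)
  vals <- (x1 - x2) / (x1 + x2)
  vals[is.nan(vals) & !is.na(x1) & !is.na(x2)] <- 0  # both powers zero
  structure(list(values = vals, freqs = freqs, times = times,
                 channels = channels),
            class = "tf_map")
}

#' Minimum-norm source estimate
#'
#' Regularized minimum-norm inverse with free-oriented dipoles: source
#' coefficients are `G' (G G' + reg I)^{-1} nu` with `G` the channels x
#' (3 * sources) gain matrix; each source's amplitude is the Euclidean norm
#' over its 3 orientation coefficients.
#'
#' @param topography a `topography` or a named/plain numeric channel
#'   vector.
#' @param leadfield a `leadfield` from [make_leadfield()] (or a compatible
#'   list with `gain` channels x sources x 3 and `source_positions`).
#' @param reg Tikhonov regularization factor (default 1e-16, essentially
#'   unregularized; raise it for noisy topographies).
#' @return a `source_estimate`: non-negative `amplitude` per source,
#'   orientation `coefficients` (3 x sources), `source_positions`.
#' @export
minimum_norm <- function(topography, leadfield, reg = 1e-16) {
  nu <- if (inherits(topography, "topography")) topography$values else topography
  gain <- leadfield$gain
  nc <- dim(gain)[1]; ns <- dim(gain)[2]
  if (!is.null(names(nu)) && !is.null(leadfield$channel_names)) {
    if (!all(leadfield$channel_names %in% names(nu))) {
      stop("leadfield channel set does not match the topography")
    }
    nu <- nu[leadfield$channel_names]
  }
  if (length(nu) != nc) stop("topography length does not match leadfield channels")
  G <- matrix(aperm(gain, c(1, 3, 2)), nc)   # columns: (orient within source)
  gram <- tcrossprod(G) + diag(reg, nc)
  rhs <- tryCatch(solve(gram, nu), error = function(e) {
    stop("singular system; use reg > 0", call. = FALSE)
  })
  coefs <- matrix(crossprod(G, rhs), nrow = 3)  # 3 x sources
  structure(list(amplitude = sqrt(colSums(coefs^2)), coefficients = coefs,
                 source_positions = leadfield$source_positions, reg = reg),
            class = "source_estimate")
}

# Default hemisphere channel sets for the time-frequency contrast (C1/C2
# centred sensorimotor areas). set = "results" is the 6-channel list,
# set = "methods" the shorter 4-channel list.
#' Hemisphere channel sets for the TF contrast
#'
#' @param hemisphere `"left"` or `"right"`.
#' @param set `"results"` (6 channels, default) or `"methods"` (4).
#' @return character vector of channel labels.
#' @export
tf_channel_set <- function(hemisphere = c("left", "right"),
                           set = c("results", "methods")) {
  hemisphere <- match.arg(hemisphere)
  set <- match.arg(set)
  left <- if (set == "results") {
    c("C1", "C3", "CCP1h", "FC1", "FCC1h", "FCC3h")
  } else c("FCC1h", "C1", "CCP1h", "FCC3h")
  if (hemisphere == "left") return(left)
  # right homologues: odd digits -> even
  vapply(left, function(ch) {
    d <- as.integer(sub("^[A-Za-z]+?([0-9]+)h?$", "\\1", ch))
    sub(as.character(d), as.character(d + 1), ch, fixed = TRUE)
  }, "", USE.NAMES = FALSE)
}
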