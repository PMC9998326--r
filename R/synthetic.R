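# Synthetic EEG/EMG sessions with known ground truth.
#
# The generator emulates the statistical structure the decoding pipeline
# assumes: 1/f background with ongoing alpha, a pre-stimulus lateralized
# 10-25 Hz amplitude modulation (ERD/ERS) plus a small hand-dependent slow
# potential shift injected through smooth scalp topographies near C1/C2,
# Markov-biased hand choices, right-skewed movement latencies with EMG
# bursts, and ocular (blink) artifacts.

#' Configuration for a synthetic reaching session
#'
#' Defaults emulate one experimental session: 1080 trials, 2.5-3.5 s jittered
#' inter-stimulus interval, lognormal movement latency with 300 ms median,
#' and sequentially biased hand choices. `effect_snr` scales both lateralized
#' effects (amplitude ratio of effect to background); `effect_snr = 0` yields
#' null data with no class information.
#'
#' @param channel_names 10-5 channel labels; default is the recommended
#'   32-channel montage plus `CPz` and the anterior pair `AFp1`/`AFp2`.
#' @param fs sampling rate, Hz (1000 by default; use 5000 to exercise the
#'   resampling stage).
#' @param n_trials number of stimuli.
#' @param iti_range c(min, max) of the uniform inter-stimulus jitter, s.
#' @param effect_snr dimensionless amplitude ratio of the lateralized effect
#'   to background; 0 gives null data.
#' @param effect_window c(start, end) in ms relative to stimulus onset in
#'   which the predictive modulation is active.
#' @param erd_band c(low, high) Hz of the modulated oscillatory band.
#' @param slow_shift_uV peak amplitude of the hand-dependent slow potential
#'   shift at `effect_snr = 1`, microvolts.
#' @param p_right probability that the first trial uses the right hand.
#' @param p_stay probability of repeating the previous hand (two-state
#'   Markov chain).
#' @param movement_latency c(median_ms, sdlog) of the lognormal
#'   stimulus-to-movement latency.
#' @param artifact_rate expected blink rate, per minute.
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   sessions.
#' @return a `synth_config` list.
#' @export
synth_config <- function(channel_names = NULL, fs = 1000, n_trials = 1080,
                         iti_range = c(2.5, 3.5), effect_snr = 1,
                         effect_window = c(-300, 150), erd_band = c(10, 25),
                         slow_shift_uV = 3, p_right = 0.5, p_stay = 0.7,
                         movement_latency = c(300, 0.25),
                         artifact_rate = 8, seed = 1) {
  if (is.null(channel_names)) {
    m <- default_montage()
    channel_names <- c(m$channels, m$reference, "AFp1", "AFp2")
  }
  if (effect_snr < 0) stop("effect_snr must be >= 0")
  if (p_right < 0 || p_right > 1 || p_stay < 0 || p_stay > 1) {
    stop("p_right and p_stay must be probabilities in [0, 1]")
  }
  if (iti_range[1] < 0 || iti_range[1] > iti_range[2]) {
    stop("iti_range must satisfy 0 <= min <= max")
  }
  if (fs <= 2 * erd_band[2]) stop("fs must exceed twice the ERD band upper edge")
  if (effect_window[1] >= effect_window[2]) stop("effect_window start must precede end")
  structure(list(channel_names = channel_names, fs = fs, n_trials = n_trials,
                 iti_range = iti_range, effect_snr = effect_snr,
                 effect_window = effect_window, erd_band = erd_band,
                 slow_shift_uV = slow_shift_uV, p_right = p_right,
                 p_stay = p_stay, movement_latency = movement_latency,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "synth_config")
}

#' Markov-biased hand-choice labels
#'
#' Draws a left/right label sequence from a two-state Markov chain: the first
#' label is right with probability `p_right`, each later label repeats its
#' predecessor with probability `p_stay` (the 2 x 2 movement matrix of
#' sequential hand-use bias).
#'
#' @param n_trials number of labels (>= 1).
#' @param p_right probability of `"R"` on the first trial.
#' @param p_stay probability of repeating the previous hand.
#' @param seed integer RNG seed.
#' @return character vector of `"L"`/`"R"` of length `n_trials`.
#' @examples
#' generate_labels(10, p_right = 0.5, p_stay = 0.8, seed = 1)
#' @export
generate_labels <- function(n_trials, p_right = 0.5, p_stay = 0.7, seed = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (p_right < 0 || p_right > 1 || p_stay < 0 || p_stay > 1) {
    stop("p_right and p_stay must be probabilities in [0, 1]")
  }
  with_seed(seed, {
    u <- stats::runif(n_trials)
    labels <- character(n_trials)
    labels[1] <- if (u[1] < p_right) "R" else "L"
    for (i in seq_len(n_trials)[-1]) {
      labels[i] <- if (u[i] < p_stay) labels[i - 1] else setdiff(c("L", "R"), labels[i - 1])
    }
    labels
  })
}

# Spectrum-shaped Gaussian noise of length n, unit variance. `shape_fn`
# maps frequency (Hz) to amplitude gain. The FFT length is padded to a
# power of two so synthesis stays O(n log n) for any requested length.
shaped_noise <- function(n, fs, shape_fn) {
  nfft <- stats::nextn(n, 2)
  f <- (0:(nfft / 2)) * fs / nfft
  shape <- shape_fn(f)
  shape[1] <- 0                                # zero DC
  re <- stats::rnorm(length(shape)); im <- stats::rnorm(length(shape))
  half <- complex(real = re, imaginary = im) * shape
  spec <- c(half, Conj(rev(half[2:(length(half) - 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# 1/f^(alpha/2)-shaped ("pink" at alpha = 1) Gaussian noise, unit variance.
one_over_f_noise <- function(n, fs, alpha = 1) {
  shaped_noise(n, fs, function(f) c(0, f[-1]^(-alpha / 2)))
}

# Band-limited Gaussian noise, unit variance.
band_noise <- function(n, fs, band) {
  shaped_noise(n, fs, function(f) as.numeric(f >= band[1] & f <= band[2]))
}

# Gaussian scalp bump centred at (cx, cy) evaluated at channel positions;
# channels without 10-5 coordinates get zero loading.
scalp_bump <- function(pos, cx, cy, sigma = 1.2) {
  v <- exp(-((pos$x - cx)^2 + (pos$y - cy)^2) / (2 * sigma^2))
  v[is.na(v)] <- 0
  v
}

# Smooth per-trial gating envelope: 1 inside [on, off] (sample indices),
# raised-cosine flanks of `ramp` samples.
gate_envelope <- function(n, on, off, ramp) {
  env <- numeric(n)
  on <- max(1L, on); off <- min(n, off)
  if (on > off) return(env)
  env[on:off] <- 1
  rise <- seq_len(ramp)
  up <- (on - ramp):(on - 1); keep <- up >= 1
  env[up[keep]] <- (0.5 - 0.5 * cos(pi * rise / ramp))[keep]
  down <- (off + 1):(off + ramp); keep <- down <= n
  env[down[keep]] <- rev(0.5 - 0.5 * cos(pi * rise / ramp))[keep]
  env
}

#' Generate a synthetic reaching session
#'
#' Builds a continuous EEG + EMG recording with the documented timing model:
#' the first stimulus occurs 3 s into the record and successive stimuli are
#' separated by movement latency + a fixed 0.7 s return-to-home dwell + a
#' uniform jitter from `iti_range`. The EEG is a sum of 1/f sensor noise,
#' spatially smooth 1/f background sources, ongoing occipital 10 Hz alpha,
#' two hemispheric 10-25 Hz sources whose amplitude is multiplicatively
#' modulated in the effect window (suppressed contralateral, enhanced
#' ipsilateral to the upcoming hand), a hand-signed slow potential bump, and
#' blink artifacts loading on the anterior channel pair. EMG channels carry
#' a broadband burst from movement onset.
#'
#' @param config a [synth_config()].
#' @return list with `recording` (an [eeg_recording()]) and `truth`, a
#'   ground-truth list: `labels`, `stim_times`, `move_times` (s),
#'   `erd_topographies` (left/right source scalp patterns),
#'   `slow_topography` (pattern whose sign flips with hand; positive over
#'   the left hemisphere for right-hand trials), `blink_topography`,
#'   `informative_channels`, `effect_window`, and `warnings`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    fs <- config$fs
    nt <- config$n_trials
    labels <- {
      u <- stats::runif(nt)
      lab <- character(nt)
      lab[1] <- if (u[1] < config$p_right) "R" else "L"
      for (i in seq_len(nt)[-1]) {
        lab[i] <- if (u[i] < config$p_stay) lab[i - 1] else setdiff(c("L", "R"), lab[i - 1])
      }
      lab
    }

    lat_med <- config$movement_latency[1] / 1000
    latency <- stats::rlnorm(nt, meanlog = log(lat_med),
                             sdlog = config$movement_latency[2])
    return_dwell <- 0.7
    gaps <- latency[-nt] + return_dwell +
      stats::runif(nt - 1, config$iti_range[1], config$iti_range[2])
    stim <- 3 + c(0, cumsum(gaps))
    move <- stim + latency
    n <- ceiling((stim[nt] + 3) * fs)

    chans <- config$channel_names
    nc <- length(chans)
    pos <- channel_positions(chans)

    # --- topographies -----------------------------------------------------
    have_c1 <- any(!is.na(pos$x) & sqrt((pos$x + 1)^2 + pos$y^2) < 1.0)
    have_c2 <- any(!is.na(pos$x) & sqrt((pos$x - 1)^2 + pos$y^2) < 1.0)
    warnings <- character(0)
    if (have_c1 && have_c2) {
      tau_L <- scalp_bump(pos, -1, 0)
      tau_R <- scalp_bump(pos, 1, 0)
    } else {
      # fall back to the most lateral frontocentral channel on each side
      fc <- !is.na(pos$y) & pos$y >= 0 & pos$y <= 2
      tau_L <- tau_R <- numeric(nc)
      il <- which(fc & pos$x < 0); ir <- which(fc & pos$x > 0)
      if (length(il) == 0 || length(ir) == 0) {
        stop("channel set has no frontocentral channels on both sides")
      }
      tau_L[il[which.max(abs(pos$x[il]))]] <- 1
      tau_R[ir[which.max(abs(pos$x[ir]))]] <- 1
      warnings <- "no C1/C2 neighborhood; lateral frontocentral fallback topographies"
    }
    names(tau_L) <- names(tau_R) <- chans
    tau_slow <- tau_L - tau_R
    tau_blink <- scalp_bump(pos, 0, 4.25, sigma = 1.0)
    tau_blink[is.na(pos$x)] <- 0
    if (max(tau_blink) > 0) tau_blink <- tau_blink / max(tau_blink)
    names(tau_blink) <- chans

    # --- background -------------------------------------------------------
    eeg <- matrix(0, nc, n)
    for (c in seq_len(nc)) eeg[c, ] <- 5 * one_over_f_noise(n, fs)
    n_bg <- 6
    for (b in seq_len(n_bg)) {
      topo <- scalp_bump(pos, stats::runif(1, -3, 3), stats::runif(1, -4, 4),
                         sigma = stats::runif(1, 1, 2)) * sample(c(-1, 1), 1)
      eeg <- eeg + (4 * topo) %o% one_over_f_noise(n, fs)
    }
    alpha_env <- 1 + 0.5 * one_over_f_noise(n, fs, alpha = 2)
    alpha <- alpha_env * sin(2 * pi * 10 * seq_len(n) / fs + stats::runif(1, 0, 2 * pi))
    eeg <- eeg + (4 * scalp_bump(pos, 0, -3.5)) %o% alpha

    # --- lateralized ERD/ERS effect --------------------------------------
    depth <- min(0.45 * config$effect_snr, 0.95)
    base_amp <- 4
    win_on <- round(config$effect_window[1] / 1000 * fs)
    win_off <- round(config$effect_window[2] / 1000 * fs)
    ramp <- max(2L, round(0.05 * fs))
    gain_L <- rep(1, n); gain_R <- rep(1, n)
    slow <- numeric(n)
    stim_idx <- round(stim * fs) + 1L
    slow_amp <- config$slow_shift_uV * config$effect_snr
    for (i in seq_len(nt)) {
      a <- stim_idx[i] + win_on; b <- stim_idx[i] + win_off
      env <- NULL  # build envelope lazily only over the affected span
      lo <- max(1L, a - ramp); hi <- min(n, b + ramp)
      loc <- gate_envelope(hi - lo + 1L, a - lo + 1L, b - lo + 1L, ramp)
      sgn <- if (labels[i] == "R") 1 else -1
      # contralateral suppression / ipsilateral enhancement
      if (labels[i] == "R") {
        gain_L[lo:hi] <- gain_L[lo:hi] * (1 - depth * loc)
        gain_R[lo:hi] <- gain_R[lo:hi] * (1 + depth * loc)
      } else {
        gain_L[lo:hi] <- gain_L[lo:hi] * (1 + depth * loc)
        gain_R[lo:hi] <- gain_R[lo:hi] * (1 - depth * loc)
      }
      # slow potential bump, hand-signed
      if (slow_amp > 0) slow[lo:hi] <- slow[lo:hi] + sgn * slow_amp * loc
    }
    src_L <- base_amp * gain_L * band_noise(n, fs, config$erd_band)
    src_R <- base_amp * gain_R * band_noise(n, fs, config$erd_band)
    eeg <- eeg + tau_L %o% src_L + tau_R %o% src_R + tau_slow %o% slow

    # --- blinks -----------------------------------------------------------
    n_blinks <- stats::rpois(1, config$artifact_rate * n / fs / 60)
    blink_src <- numeric(n)
    if (n_blinks > 0) {
      bt <- sort(stats::runif(n_blinks, 0.5, n / fs - 0.5))
      blen <- round(0.3 * fs)
      shape <- 0.5 - 0.5 * cos(2 * pi * seq_len(blen) / blen)
      for (t0 in bt) {
        i0 <- round(t0 * fs)
        idx <- i0:(i0 + blen - 1L)
        keep <- idx <= n
        blink_src[idx[keep]] <- blink_src[idx[keep]] +
          stats::runif(1, 80, 120) * shape[keep]
      }
      eeg <- eeg + tau_blink %o% blink_src
    }

    # --- EMG --------------------------------------------------------------
    emg <- matrix(stats::rnorm(2 * n, sd = 1), 2, n)
    move_idx <- round(move * fs) + 1L
    blen <- round(0.4 * fs)
    burst_env <- c(seq(0, 1, length.out = round(0.02 * fs)),
                   rep(1, blen - round(0.02 * fs)))
    burst_env <- burst_env * exp(-seq_along(burst_env) / (0.3 * fs))
    for (i in seq_len(nt)) {
      row <- if (labels[i] == "R") 2L else 1L
      idx <- move_idx[i]:(move_idx[i] + length(burst_env) - 1L)
      keep <- idx <= n
      emg[row, idx[keep]] <- emg[row, idx[keep]] +
        50 * burst_env[keep] * stats::rnorm(sum(keep))
    }

    informative <- chans[pmax(tau_L, tau_R) > 0.5 * max(pmax(tau_L, tau_R))]
    rec <- eeg_recording(eeg, fs, chans, events = stim, labels = labels,
                         emg = list(data = emg, channels = c("EMGl", "EMGr")),
                         meta = list(synthetic = TRUE, seed = config$seed,
                                     warnings = warnings))
    truth <- list(labels = labels, stim_times = stim, move_times = move,
                  erd_topographies = list(left = tau_L, right = tau_R),
                  slow_topography = tau_slow, blink_topography = tau_blink,
                  informative_channels = informative,
                  effect_window = config$effect_window, warnings = warnings)
    list(recording = rec, truth = truth)
  })
}

#' Synthetic leadfield (forward gain) matrix
#'
#' Builds a smooth random gain array for `n_sources` free-orientation
#' dipoles: each source has a Gaussian scalp pattern plus its two tangential
#' derivative patterns as the three orientation columns. A synthetic
#' stand-in for a boundary-element head model, sufficient for exercising the
#' minimum-norm inverse.
#'
#' @param n_channels number of channels, or supply `channel_names`.
#' @param n_sources number of sources (>= 1).
#' @param seed integer RNG seed; identical seeds give identical leadfields.
#' @param channel_names optional 10-5 labels (length `n_channels`); default
#'   is a regular grid of nominal positions.
#' @return list of class `leadfield` with `gain` (channels x sources x 3),
#'   `source_positions` (n_sources x 3) and `channel_names`.
#' @export
make_leadfield <- function(n_channels, n_sources, seed = 1,
                           channel_names = NULL) {
  if (n_sources < 1) stop("n_sources must be >= 1")
  if (!is.null(channel_names)) {
    pos <- channel_positions(channel_names)
    if (anyNA(pos$x)) stop("all channel_names must be 10-5 labels")
    n_channels <- length(channel_names)
  } else {
    nx <- ceiling(sqrt(n_channels))
    grid <- expand.grid(x = seq(-3, 3, length.out = nx),
                        y = seq(-4, 4, length.out = ceiling(n_channels / nx)))
    pos <- grid[seq_len(n_channels), ]
    channel_names <- sprintf("ch%02d", seq_len(n_channels))
  }
  with_seed(seed, {
    gain <- array(0, c(n_channels, n_sources, 3))
    src <- matrix(0, n_sources, 3)
    for (s in seq_len(n_sources)) {
      cx <- stats::runif(1, -2.5, 2.5); cy <- stats::runif(1, -3.5, 3.5)
      sigma <- stats::runif(1, 0.8, 1.5)
      base <- exp(-((pos$x - cx)^2 + (pos$y - cy)^2) / (2 * sigma^2))
      gain[, s, 1] <- base
      gain[, s, 2] <- -(pos$x - cx) / sigma^2 * base
      gain[, s, 3] <- -(pos$y - cy) / sigma^2 * base
      src[s, ] <- c(cx, cy, 0.5)
    }
    # guard the no-all-zero-channel-row invariant
    norms <- sqrt(rowSums(matrix(gain, n_channels)^2))
    if (any(norms == 0)) gain[norms == 0, 1, 1] <- 1e-6
    structure(list(gain = gain, source_positions = src,
                   channel_names = channel_names),
              class = "leadfield")
  })
}
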