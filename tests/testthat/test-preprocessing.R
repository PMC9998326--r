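# Preprocessing: filter frequency response, epoch bookkeeping, resampling,
# pre-stimulus-only rejection/cleaning, EMG onset detection.

test_that("zero-phase FIR filters have the contracted frequency response", {
  fs <- 1000
  n <- 4000
  mid <- 1500:2500  # away from the zero-padded edges

  # high-pass removes DC essentially exactly
  const <- eeg_recording(matrix(5, 1, n), fs, "Cz")
  hp <- fir_filter(const, "highpass", 1)
  expect_lt(max(abs(hp$data[1, mid])), 5 * 1e-6)

  # low-pass at 45 Hz attenuates a 60 Hz sine below 5% RMS
  t <- (1:n) / fs
  s60 <- eeg_recording(matrix(sin(2 * pi * 60 * t), 1), fs, "Cz")
  lp <- fir_filter(s60, "lowpass", 45)
  expect_lt(sqrt(mean(lp$data[1, mid]^2)) / sqrt(0.5), 0.05)

  # 10 Hz passes the high-pass + low-pass cascade within 2% amplitude
  s10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "Cz")
  out <- fir_filter(fir_filter(s10, "highpass", 1), "lowpass", 45)
  amp <- max(abs(out$data[1, mid]))
  expect_lt(abs(amp - 1), 0.02)

  expect_error(fir_filter(s10, "lowpass", 600), "Nyquist")
})

test_that("epoch extraction aligns t = 0 with the stimulus sample", {
  fs <- 1000
  events <- seq(6, 60, by = 6)[1:10]
  rec <- eeg_recording(matrix(rnorm(2 * 66000), 2), fs, c("C1", "C2"),
                       events = events,
                       labels = rep(c("L", "R"), 5))
  ep <- extract_epochs(rec, 2.5, 2.5)
  expect_equal(dim(ep$data), c(10, 2, 5001))
  expect_true(0 %in% ep$times)

  # an impulse at the event sample lands exactly at t = 0
  imp <- matrix(0, 1, 5000)
  imp[1, round(2 * fs) + 1] <- 7
  rec2 <- eeg_recording(imp, fs, "Cz", events = 2)
  ep2 <- extract_epochs(rec2, 1, 1)
  expect_equal(as.numeric(ep2$data[1, 1, ep2$times == 0]), 7)

  # events too close to the record edge are dropped, others kept
  rec3 <- eeg_recording(matrix(rnorm(9000), 1), fs, "Cz",
                        events = c(1, 5), labels = c("L", "R"))
  ep3 <- extract_epochs(rec3, 2.5, 2.5)
  expect_equal(dim(ep3$data)[1], 1)
  expect_equal(attr(ep3, "dropped"), 1L)
  expect_equal(ep3$labels, "R")
})

test_that("resampling is anti-aliased and preserves t = 0", {
  fs <- 5000
  n <- 25001
  t <- (0:(n - 1)) / fs - 2.5
  x <- array(sin(2 * pi * 2 * t), c(1, 1, n))
  ep <- eeg_epochs(x, t * 1000, fs, "Cz")
  down <- resample_epochs(ep, 1000)
  expect_equal(dim(down$data)[3], 5001)
  expect_true(0 %in% down$times)
  ref <- sin(2 * pi * 2 * down$times / 1000)
  mid <- 1000:4000
  expect_lt(max(abs(down$data[1, 1, mid] - ref[mid])), 0.01)

  # identity when rates match
  expect_identical(resample_epochs(ep, fs), ep)
})

test_that("outlier rejection uses pre-stimulus data only", {
  set.seed(5)
  ep <- noise_epochs(24, sprintf("ch%02d", 1:8), n_times = 200,
                     labels = rep(c("L", "R"), 12))
  # plant a 100x variance channel
  bad <- ep
  bad$data[, 3, ] <- bad$data[, 3, ] * 10
  res <- reject_outliers(bad, z_thresh = 3.5)
  expect_equal(res$report$channels_removed, "ch03")
  expect_equal(length(res$report$trials_removed), 0)

  # clean Gaussian data at a lax threshold: nothing removed
  res2 <- reject_outliers(ep, z_thresh = 10)
  expect_equal(length(res2$report$channels_removed), 0)
  expect_equal(length(res2$report$trials_removed), 0)

  # artifact confined to post-stimulus samples is NOT removed, and the
  # decision pattern is unchanged (cleaning causality)
  post <- ep
  post$data[5, , ep$times > 0] <- post$data[5, , ep$times > 0] + 50
  res3 <- reject_outliers(post, z_thresh = 3.5)
  res0 <- reject_outliers(ep, z_thresh = 3.5)
  expect_equal(res3$report$channels_removed, res0$report$channels_removed)
  expect_equal(res3$report$trials_removed, res0$report$trials_removed)

  # unconditional peripheral exclusion
  res4 <- reject_outliers(ep, z_thresh = 10, exclude_channels = "ch08")
  expect_equal(res4$report$channels_removed, "ch08")
})

test_that("re-referencing satisfies its algebraic contracts", {
  ep <- noise_epochs(4, c("C1", "C2", "CPz", "Fz"), n_times = 50)
  avg <- rereference(ep, "average")
  sums <- apply(avg$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  # idempotence
  avg2 <- rereference(avg, "average")
  expect_equal(avg2$data, avg$data, tolerance = 1e-12)

  # all channels equal to CPz -> all zeros after CPz referencing
  eq <- ep
  for (c in 1:4) eq$data[, c, ] <- eq$data[, 3, ]
  cpz <- rereference(eq, "CPz")
  expect_equal(cpz$channels, c("C1", "C2", "Fz"))
  expect_lt(max(abs(cpz$data)), 1e-12)
  expect_equal(cpz$reference, "CPz")

  expect_error(rereference(ep, "TP10"), "not present")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- noise_epochs(3, c("C1", "C2", "Cz"), n_times = 80)
  ep$data <- ep$data + 13
  bc <- baseline_correct(ep)
  pre_means <- apply(bc$data[, , bc$times < 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(pre_means)), 1e-12)
})

test_that("cleaning ICA recovers and removes a planted blink component", {
  ses <- std_session(1, n_trials = 60, seed = 31, artifact_rate = 12)
  ep <- prep_epochs(ses, pre = 1.2, post = 0.4, ref = NULL)
  ep <- rereference(ep, "average")
  res <- suppressWarnings(clean_ica(ep, 50, remove = "auto_ocular"))
  removed <- res$model$removed_component_indices
  expect_gte(length(removed), 1)
  tau <- ses$truth$blink_topography[ep$channels]
  r <- max(abs(cor(res$model$mixing[, removed, drop = FALSE], tau)))
  expect_gt(r, 0.9)

  # a removed component's time course is absent from the cleaned data
  i <- removed[1]
  Xc <- matrix(aperm(res$epochs$data, c(2, 1, 3)), length(ep$channels))
  X0 <- matrix(aperm(ep$data, c(2, 1, 3)), length(ep$channels))
  s_clean <- drop(res$model$demixing[i, , drop = FALSE] %*%
                    (Xc - res$model$mean))
  s_orig <- drop(res$model$demixing[i, , drop = FALSE] %*%
                   (X0 - res$model$mean))
  expect_lt(var(s_clean), 1e-6 * var(s_orig))

  # remove = nothing: cleaned data equal the compressed-subspace projection
  res0 <- suppressWarnings(clean_ica(ep, 50, remove = integer(0)))
  proj <- res0$model$mixing %*% (res0$model$demixing %*% (X0 - res0$model$mean)) +
    res0$model$mean
  expect_equal(matrix(aperm(res0$epochs$data, c(2, 1, 3)),
                      length(ep$channels)),
               proj, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("EMG onset is the first crossing of half the envelope maximum", {
  fs <- 1000
  n <- 1500
  stim <- 0.5
  emg <- rnorm(n, sd = 0.01)
  burst <- 801:1100  # +300 ms after stimulus, instant rise
  emg[burst] <- emg[burst] + 40 * rnorm(length(burst))
  onset <- detect_movement_onset(emg, fs, stim)
  expect_lt(abs(onset - 300), 15)

  expect_true(is.na(detect_movement_onset(numeric(n), fs, stim)))

  # two bursts: the first (larger) one wins even though both cross
  emg2 <- rnorm(n, sd = 0.01)
  emg2[801:950] <- emg2[801:950] + 40 * rnorm(150)
  emg2[1301:1450] <- emg2[1301:1450] + 25 * rnorm(150)
  expect_lt(abs(detect_movement_onset(emg2, fs, stim) - 300), 20)
})
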