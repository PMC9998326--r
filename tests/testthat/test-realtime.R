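# Causal real-time simulation: calibration indexing, strict causality,
# and calibration/test isolation.

rt_epochs <- function(labels, n_times = 401, seed = 5) {
  set.seed(seed)
  n <- length(labels)
  chans <- c("C1", "C2", "Cz", "C4")
  data <- array(rnorm(n * 4 * n_times), c(n, 4, n_times))
  # weak class signal so predictions are non-degenerate
  data[labels == "R", 1, ] <- data[labels == "R", 1, ] + 0.5
  eeg_epochs(data, times = seq(-200, 200, length.out = n_times), fs = 1000,
             channels = chans, labels = labels)
}

test_that("calibration spans the first n occurrences of each class", {
  labels <- rep(c("R", "L"), 150)
  ep <- rt_epochs(labels)
  res <- suppressWarnings(simulate_realtime(ep, labels, "pre_movement",
                                            n_calib_per_class = 100, M = 3))
  expect_equal(res$n_calibration_trials, 200)
  expect_equal(res$predictions$trial, 201:300)
  expect_equal(res$n_test_trials, 100)
  expect_false(res$excluded)
  # all test trials strictly after the last calibration trial
  expect_true(all(res$predictions$trial > 200))

  # unbalanced stream: trials of the early-complete class between
  # calibration completion points are neither calibrated nor tested
  lab2 <- c(rep("R", 120), rep(c("L", "R"), 110))
  ep2 <- rt_epochs(lab2, seed = 6)
  res2 <- suppressWarnings(simulate_realtime(ep2, lab2, "pre_movement",
                                             n_calib_per_class = 100, M = 3))
  last_calib <- which(lab2 == "L")[100]
  expect_equal(res2$predictions$trial[1], last_calib + 1)

  expect_error(suppressWarnings(
    simulate_realtime(ep, labels, n_calib_per_class = 200)), "class")
  res3 <- suppressWarnings(simulate_realtime(ep, labels, "pre_movement",
                                             n_calib_per_class = 145, M = 3))
  expect_true(res3$excluded)  # only 10 testable trials
})

test_that("predictions are causal: samples after the window never matter", {
  labels <- rep(c("R", "L"), 80)
  ep <- rt_epochs(labels, seed = 7)
  for (mode in c("pre_movement", "pre_visual")) {
    res <- suppressWarnings(simulate_realtime(ep, labels, mode,
                                              n_calib_per_class = 50, M = 3))
    cut <- res$window$end_ms
    pert <- ep
    late <- ep$times > cut
    set.seed(99)
    pert$data[, , late] <- pert$data[, , late] +
      array(rnorm(sum(late) * 160 * 4, sd = 50), c(160, 4, sum(late)))
    res_p <- suppressWarnings(simulate_realtime(pert, labels, mode,
                                                n_calib_per_class = 50, M = 3))
    expect_identical(res$predictions$prediction, res_p$predictions$prediction)
    expect_equal(res$predictions$score, res_p$predictions$score)
  }
})

test_that("deleting test trials does not change the calibrated model", {
  labels <- rep(c("R", "L"), 70)
  ep <- rt_epochs(labels, seed = 8)
  res <- suppressWarnings(simulate_realtime(ep, labels, "pre_visual",
                                            n_calib_per_class = 50, M = 3))
  trunc <- select_trials(ep, 1:100)
  res_t <- suppressWarnings(simulate_realtime(trunc, labels[1:100],
                                              "pre_visual",
                                              n_calib_per_class = 50, M = 3))
  expect_identical(res$classifier$weights, res_t$classifier$weights)
  expect_identical(res$feature_model$W, res_t$feature_model$W)
  expect_true(res_t$excluded)  # no test trials remain
  expect_equal(res_t$n_test_trials, 0)
})

test_that("realtime accuracy tracks the offline estimate on stationary data", {
  ses <- std_session(2, n_trials = 140, seed = 101)
  ep <- prep_epochs(ses)
  rt <- suppressWarnings(simulate_realtime(ep, ep$labels, "pre_movement",
                                           n_calib_per_class = 45))
  offline <- quick_accuracy(ep)
  expect_false(rt$excluded)
  expect_lt(abs(rt$accuracy - offline), 0.15)
  expect_gt(rt$accuracy, 0.8)
})
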