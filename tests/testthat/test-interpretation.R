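# Interpretation outputs: topography mapping, Morlet class contrast,
# minimum-norm inversion.

fake_ica_model <- function(K_inv, channels) {
  M <- ncol(K_inv)
  structure(list(M = M, compression = pinv(K_inv), decompression = K_inv,
                 comp_mean = rep(0, length(channels)), W = diag(M),
                 A = diag(M), evoked_template = NULL,
                 component_templates = NULL,
                 window = window_spec(-150, 150), channels = channels,
                 fs = 1000, seed = 1), class = "feature_ica_model")
}

fake_classifier <- function(weights, M) {
  structure(list(weights = weights, intercept = 0, penalty = "l1",
                 lambda = 0.1, center = rep(0, 2 * M),
                 scale = rep(1, 2 * M), standardize = TRUE,
                 feature_backend = "ica", n_features = 2 * M),
            class = "classifier_model")
}

test_that("a single mean-feature weight maps to that component's mixing column", {
  chans <- c("C1", "C2", "Cz", "CP1")
  K_inv <- matrix(c(1, -2, 0.5, 3), 4, 1)
  fm <- fake_ica_model(K_inv, chans)
  clf <- fake_classifier(c(1, 0), M = 1)
  nu <- classifier_topography(fm, clf)
  cs <- sum(nu$values * K_inv[, 1]) /
    sqrt(sum(nu$values^2) * sum(K_inv[, 1]^2))
  expect_equal(abs(cs), 1, tolerance = 1e-12)
  # sign convention: the strongest left-hemisphere channel is positive
  pos <- channel_positions(chans)
  left <- which(pos$x < 0)
  expect_gt(nu$values[left[which.max(abs(nu$values[left]))]], 0)

  expect_error(classifier_topography(fm, fake_classifier(rep(0, 4), M = 2)),
               "feature model")
})

test_that("topography is invariant (up to scale) to feature rescaling", {
  ses <- std_session(2, n_trials = 140, seed = 101)
  ep <- prep_epochs(ses)
  split <- prepare_datasets(ep$labels, 0.2, seed = 2)
  train <- select_trials(ep, split$train_idx)
  fm <- suppressWarnings(fit_feature_ica(train, window_spec(-150, 150),
                                         M = 30, seed = 1))
  f <- ica_features(train, fm)
  labels <- ep$labels[split$train_idx]
  clf1 <- fit_logistic_cv(f, labels, seed = 1)
  f10 <- feature_matrix(f$values * 10, f$descriptors, f$backend)
  clf2 <- fit_logistic_cv(f10, labels, seed = 1)
  nu1 <- classifier_topography(fm, clf1)$values
  nu2 <- classifier_topography(fm, clf2)$values
  cs <- abs(sum(nu1 * nu2)) / sqrt(sum(nu1^2) * sum(nu2^2))
  expect_gt(cs, 0.999)
})

test_that("the normalized TF contrast has its algebraic properties", {
  fs <- 500
  times <- seq(-500, 500, by = 1000 / fs)
  n_t <- length(times)
  make_ep <- function(amp, seed) {
    set.seed(seed)
    d <- array(0, c(8, 2, n_t))
    for (i in 1:8) for (c in 1:2) {
      d[i, c, ] <- amp * sin(2 * pi * 20 * times / 1000 + runif(1, 0, 2 * pi))
    }
    eeg_epochs(d, times, fs, c("C1", "C2"))
  }
  # right-hand trials with doubled 20 Hz power (amplitude sqrt(2))
  epR <- make_ep(sqrt(2), 1)
  epL <- make_ep(1, 2)
  tf <- tf_difference(epR, epL, c("C1", "C2"), f_lo = 8, f_hi = 30)
  v <- tf$values[tf$freqs == 20, ]
  expect_lt(max(abs(v[!is.na(v)] - 1 / 3)), 0.02)
  expect_true(all(abs(tf$values[!is.na(tf$values)]) <= 1))

  # identical classes give a zero map
  tf0 <- tf_difference(epR, epR, c("C1", "C2"), f_lo = 8, f_hi = 30)
  expect_equal(max(abs(tf0$values[!is.na(tf0$values)])), 0)

  # antisymmetry under class swap
  set.seed(3)
  epA <- make_ep(1.3, 4); epB <- make_ep(0.9, 5)
  t1 <- tf_difference(epA, epB, c("C1", "C2"), f_lo = 8, f_hi = 30)
  t2 <- tf_difference(epB, epA, c("C1", "C2"), f_lo = 8, f_hi = 30)
  expect_equal(t1$values, -t2$values, tolerance = 1e-10)

  expect_error(tf_difference(epR, epL, "C1", f_hi = 300), "Nyquist")
  expect_error(tf_difference(epR, epL, "F9"), "not present")
})

test_that("minimum-norm inversion matches the pseudoinverse least-norm solution", {
  # well-conditioned toy gain: 4 channels, 3 free-orientation sources
  set.seed(6)
  lf <- list(gain = array(rnorm(4 * 3 * 3), c(4, 3, 3)),
             source_positions = matrix(rnorm(9), 3), channel_names = NULL)
  G <- matrix(aperm(lf$gain, c(1, 3, 2)), 4)
  nu <- rnorm(4)
  est <- minimum_norm(nu, lf, reg = 1e-16)
  oracle <- drop(pinv(G) %*% nu)
  expect_lt(max(abs(as.vector(est$coefficients) - oracle)), 1e-8)

  # zero topography -> zero estimate; linearity in the topography
  expect_equal(minimum_norm(rep(0, 4), lf)$amplitude, rep(0, 3))
  est2 <- minimum_norm(2 * nu, lf, reg = 1e-12)
  est1 <- minimum_norm(nu, lf, reg = 1e-12)
  expect_equal(as.vector(est2$coefficients), 2 * as.vector(est1$coefficients),
               tolerance = 1e-6)
})

test_that("a single active source is localized at its own position", {
  lf <- make_leadfield(36, 8, seed = 9)
  for (s in seq_len(8)) {
    nu <- lf$gain[, s, 1] + 0.5 * lf$gain[, s, 2]
    est <- minimum_norm(nu, lf, reg = 1e-10)
    expect_equal(which.max(est$amplitude), s)
  }
  # rank-deficient system without regularization is refused
  lf1 <- make_leadfield(10, 1, seed = 2)
  expect_error(minimum_norm(rnorm(10), lf1, reg = 0), "reg")
})

test_that("hemispheric ERD reverses the sign of the TF contrast", {
  ses <- std_session(2, n_trials = 140, seed = 101)
  ep <- prep_epochs(ses, pre = 1.0, post = 0.4)
  idxR <- which(ep$labels == "R")[1:40]
  idxL <- which(ep$labels == "L")[1:40]
  left_set <- c("C1", "C3", "FC1", "FCC1h")
  right_set <- c("C2", "C4", "FC2", "FCC2h")
  band <- function(channels) {
    tf <- tf_difference(select_trials(ep, idxR), select_trials(ep, idxL),
                        channels, f_lo = 10, f_hi = 25,
                        t_window = c(-150, 150))
    mean(tf$values, na.rm = TRUE)
  }
  lh <- band(left_set); rh <- band(right_set)
  # right-hand choice: ERD contralateral (left hemisphere power drops)
  expect_lt(lh, 0)
  expect_gt(rh, 0)
})
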