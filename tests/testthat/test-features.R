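# Feature backends: spatiotemporal PCA against a brute-force oracle, and
# ICA mean/variance features with evoked subtraction.

test_that("spatiotemporal PCA equals a brute-force covariance eigendecomposition", {
  set.seed(3)
  ep <- noise_epochs(5, c("C1", "C2", "Cz"), n_times = 9)
  w <- window_spec(ep$times[2], ep$times[8])
  basis <- fit_spatiotemporal_pca(ep, w, M = 5)

  # oracle: explicit covariance of the channel-major trial vectors
  idx <- which(ep$times >= w$start_ms & ep$times <= w$end_ms)
  V <- t(vapply(1:5, function(i) as.vector(t(ep$data[i, , idx])),
                numeric(3 * length(idx))))
  eig <- eigen(cov(V), symmetric = TRUE)
  expect_lt(max(abs(basis$eigenvalues - eig$values[1:basis$M])), 1e-10)

  # single-instant window: vector length equals the channel count
  b1 <- suppressWarnings(fit_spatiotemporal_pca(
    ep, window_spec(ep$times[4] - 0.4, ep$times[4] + 0.4), M = 2))
  expect_equal(nrow(b1$eigenvectors), 3)
})

test_that("spatiotemporal projections reconstruct and decorrelate", {
  set.seed(4)
  # rank-2 data: 2 latent factors drive all channels/times
  n <- 12
  F2 <- matrix(rnorm(n * 2), n)
  L <- matrix(rnorm(2 * 4 * 7), 2)
  ep <- eeg_epochs(array(F2 %*% L, c(n, 4, 7)), times = -3:3, fs = 1000,
                   channels = c("C1", "C2", "C3", "C4"))
  w <- window_spec(-3, 3)
  basis <- suppressWarnings(fit_spatiotemporal_pca(ep, w, M = 2))
  f <- st_features(ep, basis)
  recon <- f$values %*% t(basis$eigenvectors)
  V <- t(vapply(1:n, function(i) as.vector(t(ep$data[i, , ])), numeric(28)))
  expect_lt(max(abs(recon + rep(basis$mean, each = n) - V)), 1e-9)

  # a trial equal to the training mean maps to the zero feature row
  epm <- ep
  mean_mat <- matrix(basis$mean, nrow = 7)  # time x channel (channel-major)
  epm$data[1, , ] <- t(mean_mat)
  fz <- st_features(epm, basis)
  expect_lt(max(abs(fz$values[1, ])), 1e-9)

  # PCA features are uncorrelated on the training data
  set.seed(9)
  ep2 <- noise_epochs(40, c("C1", "C2", "C3"), n_times = 11)
  b2 <- fit_spatiotemporal_pca(ep2, window_spec(-4, 4), M = 6)
  f2 <- st_features(ep2, b2)
  cc <- cor(f2$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("feature ICA recovers a known mixing up to sign and permutation", {
  set.seed(8)
  n_tr <- 60; n_t <- 50; M0 <- 3
  # super-Gaussian sources, fixed channel mixing, no noise
  S <- array(rnorm(n_tr * M0 * n_t)^3, c(M0, n_tr * n_t))
  A0 <- matrix(rnorm(5 * M0), 5)
  X <- A0 %*% S
  dat <- aperm(array(X, c(5, n_tr, n_t)), c(2, 1, 3))
  ep <- eeg_epochs(dat, times = seq(-24.5, 24.5), fs = 1000,
                   channels = sprintf("ch%d", 1:5))
  fm <- suppressWarnings(fit_feature_ica(ep, window_spec(-24.5, 24.5), M = 3))
  mix_chan <- fm$decompression %*% fm$A   # channels x components
  r <- abs(cor(mix_chan, A0))
  # every true column matched by some estimated column
  expect_true(all(apply(r, 2, max) > 0.95))

  # W A = identity; same seed reproduces the model exactly
  expect_lt(max(abs(fm$W %*% fm$A - diag(3))), 1e-6)
  fm2 <- suppressWarnings(fit_feature_ica(ep, window_spec(-24.5, 24.5), M = 3))
  expect_identical(fm$W, fm2$W)
})

test_that("ICA features are ordered means then variances with 2M columns", {
  ep <- noise_epochs(30, sprintf("c%02d", 1:6), n_times = 41,
                     labels = rep(c("L", "R"), 15))
  fm <- suppressWarnings(fit_feature_ica(ep, window_spec(-10, 10), M = 30))
  expect_equal(fm$M, 6)  # clipped to the channel count (full-rank data)
  f <- ica_features(ep, fm)
  expect_equal(ncol(f$values), 2 * fm$M)
  expect_equal(f$descriptors$statistic,
               rep(c("mean", "variance"), each = fm$M))

  # hand-computed mean/variance from the model operators
  i <- 4
  idx <- which(ep$times >= -10 & ep$times <= 10)
  D <- fm$W %*% fm$compression
  Si <- D %*% (ep$data[i, , idx] - fm$comp_mean)
  expect_lt(max(abs(f$values[i, 1:fm$M] - rowMeans(Si))), 1e-12)
  expect_lt(max(abs(f$values[i, fm$M + (1:fm$M)] -
                      rowMeans((Si - fm$component_templates)^2))), 1e-12)

  # a trial equal to the training average epoch has ~zero variance features
  epm <- ep
  epm$data[1, , idx] <- apply(ep$data[, , idx], c(2, 3), mean)
  fz <- ica_features(epm, fm)
  expect_lt(max(abs(fz$values[1, fm$M + (1:fm$M)])), 1e-12)

  fm_bad <- fm
  fm_bad$window <- window_spec(-900, 0)
  expect_error(ica_features(ep, fm_bad), "window")
})

test_that("evoked subtraction makes variance features invariant to common waveforms", {
  set.seed(12)
  ep <- noise_epochs(24, c("C1", "C2", "C3", "C4"), n_times = 31)
  w <- window_spec(-10, 10)
  fm1 <- suppressWarnings(fit_feature_ica(ep, w, M = 3))
  f1 <- ica_features(ep, fm1)

  shifted <- ep
  common <- matrix(sin(seq(0, 4 * pi, length.out = 31)), 4, 31,
                   byrow = TRUE) * (1:4)
  for (i in 1:24) shifted$data[i, , ] <- shifted$data[i, , ] + common
  fm2 <- suppressWarnings(fit_feature_ica(shifted, w, M = 3))
  f2 <- ica_features(shifted, fm2)

  M <- fm1$M
  # variance features unchanged (up to component matching; compare sorted)
  expect_equal(apply(f1$values[, M + (1:M)], 1, sort),
               apply(f2$values[, M + (1:M)], 1, sort), tolerance = 1e-6)
  # the evoked template absorbs the added waveform
  idx <- which(ep$times >= w$start_ms & ep$times <= w$end_ms)
  expect_equal(fm2$evoked_template - fm1$evoked_template, common[, idx],
               tolerance = 1e-8, ignore_attr = TRUE)
})
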