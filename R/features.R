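# Feature extraction backends: spatiotemporal PCA, and independent-component
# mean/variance features with evoked subtraction.

# Channel-major spatiotemporal vectorization: all time points of channel 1,
# then channel 2, ... One row per trial.
st_vectorize <- function(epochs, idx) {
  d <- dim(epochs$data)
  out <- matrix(0, d[1], d[2] * length(idx))
  for (i in seq_len(d[1])) {
    out[i, ] <- as.vector(t(matrix(epochs$data[i, , idx], nrow = d[2])))
  }
  out
}

#' Fit a spatiotemporal PCA basis
#'
#' Concatenates each training trial's channels x window matrix into one long
#' spatiotemporal vector (channel-major order), removes the training mean,
#' and retains the eigenvectors of the sample covariance (1/(n-1)
#' normalization) belonging to the M largest eigenvalues. When the window
#' contains a single time instant the vector length equals the channel
#' count.
#'
#' @param train_epochs training [eeg_epochs()].
#' @param window a [window_spec()].
#' @param M number of components to retain; clipped to the data rank with a
#'   warning if too large.
#' @return a `pca_basis`: orthonormal `eigenvectors`
#'   ((channels * window samples) x M), non-increasing `eigenvalues`,
#'   training `mean`, `window`, `channels`, `fs`.
#' @export
fit_spatiotemporal_pca <- function(train_epochs, window, M) {
  idx <- window_samples(train_epochs, window)
  V <- st_vectorize(train_epochs, idx)
  mu <- colMeans(V)
  Vc <- sweep(V, 2, mu)
  sv <- svd(Vc)
  ev <- sv$d^2 / max(1, nrow(V) - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (M > rank) {
    warning(sprintf("M = %d exceeds data rank %d; clipped", M, rank))
    M <- rank
  }
  vec <- sv$v[, seq_len(M), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(M)) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(M = M, eigenvectors = vec, eigenvalues = ev[seq_len(M)],
                 mean = mu, window = window, channels = train_epochs$channels,
                 fs = train_epochs$fs),
            class = "pca_basis")
}

#' Spatiotemporal PCA features
#'
#' Projects each trial's spatiotemporal vector onto the training basis; the
#' compressed coordinates are used directly as features (M features per
#' trial).
#'
#' @param epochs an [eeg_epochs()] sharing the basis' channel set and rate.
#' @param basis a `pca_basis` from [fit_spatiotemporal_pca()].
#' @return a `feature_matrix` (trials x M).
#' @export
st_features <- function(epochs, basis) {
  check_compatible(epochs, basis)
  idx <- window_samples(epochs, basis$window)
  V <- st_vectorize(epochs, idx)
  vals <- sweep(V, 2, basis$mean) %*% basis$eigenvectors
  feature_matrix(vals, data.frame(component = seq_len(basis$M),
                                  statistic = "pc"), "st_pca")
}

#' Fit the ICA feature-extraction model
#'
#' The average training epoch is subtracted from every trial (evoked
#' subtraction, which removes bias from activity phase-locked to the
#' stimulus), the result is compressed by spatial PCA with whitening to `M`
#' dimensions, and fixed-point ICA (symmetric orthogonalization, tanh
#' contrast) estimates the component rotation. Both the compression and the
#' rotation are estimated from the evoked-subtracted data, which makes the
#' extracted variance features exactly invariant to any waveform common to
#' all trials. The model stores the demixing/mixing pair, the evoked
#' template, and each component's average time course over the training
#' trials.
#'
#' `M` is capped at the channel count and further reduced to the effective
#' rank of the windowed data (average-referenced data, for instance, has
#' rank `channels - 1`); it is never below 1.
#'
#' @param train_epochs training [eeg_epochs()].
#' @param window a [window_spec()].
#' @param M number of independent components (default 30).
#' @param seed,tol,max_iter,n_restarts ICA settings (restarts use fresh
#'   random rotations on non-convergence).
#' @return a `feature_ica_model`.
#' @export
fit_feature_ica <- function(train_epochs, window, M = 30, seed = 1,
                            tol = 1e-4, max_iter = 200, n_restarts = 1) {
  idx <- window_samples(train_epochs, window)
  d <- dim(train_epochs$data)
  # cap at the channel count; rank-deficient data (e.g. average-referenced,
  # where rank = channels - 1) is clipped further by the whitening step
  M <- max(1L, min(M, d[2]))
  nt <- d[1]; nw <- length(idx)
  # channels x (trials * window samples); trials vary fastest
  X <- matrix(aperm(train_epochs$data[, , idx, drop = FALSE], c(2, 1, 3)), d[2])
  evoked <- apply(train_epochs$data[, , idx, drop = FALSE], c(2, 3), mean)
  Xs <- array(X, c(d[2], nt, nw))
  for (t in seq_len(nw)) Xs[, , t] <- Xs[, , t] - evoked[, t]
  Xs <- matrix(Xs, d[2])                   # evoked-subtracted concatenation
  wh <- pca_whiten(Xs, M, warn = FALSE)    # mean of Xs is exactly zero
  M <- wh$M
  ica <- fastica_symm(wh$K %*% Xs, contrast = "tanh", tol = tol,
                      max_iter = max_iter, seed = seed,
                      n_restarts = n_restarts)
  W <- ica$W
  mu_c <- rowMeans(X)                      # raw channel offsets for demixing
  # component average time courses over training trials
  templates <- (W %*% wh$K) %*% (evoked - mu_c)
  structure(list(M = M, compression = wh$K, decompression = wh$K_inv,
                 comp_mean = mu_c, W = W, A = t(W),
                 evoked_template = evoked, component_templates = templates,
                 window = window, channels = train_epochs$channels,
                 fs = train_epochs$fs, seed = seed,
                 iterations = ica$iterations),
            class = "feature_ica_model")
}

#' Independent-component mean/variance features
#'
#' For each trial and component: (a) the mean of the demixed component time
#' course over the window; (b) the variance of the component after
#' subtracting that component's training-average time course, computed as
#' the mean of squares (the mean-subtracted component is assumed to be
#' zero-mean, so no per-trial recentering is applied; 1/N normalization).
#' Features are ordered means(1..M) then variances(1..M), i.e. 2M features.
#'
#' @param epochs an [eeg_epochs()] compatible with the model.
#' @param model a `feature_ica_model` from [fit_feature_ica()].
#' @return a `feature_matrix` (trials x 2M).
#' @export
ica_features <- function(epochs, model) {
  check_compatible(epochs, model)
  idx <- window_samples(epochs, model$window)
  d <- dim(epochs$data)
  means <- matrix(0, d[1], model$M)
  vars <- matrix(0, d[1], model$M)
  D <- model$W %*% model$compression       # components x channels
  for (i in seq_len(d[1])) {
    Xi <- matrix(epochs$data[i, , idx], nrow = d[2]) - model$comp_mean
    Si <- D %*% Xi
    means[i, ] <- rowMeans(Si)
    vars[i, ] <- rowMeans((Si - model$component_templates)^2)
  }
  feature_matrix(cbind(means, vars),
                 data.frame(component = rep(seq_len(model$M), 2),
                            statistic = rep(c("mean", "variance"),
                                            each = model$M)),
                 "ica")
}

#' Feature matrix container
#'
#' @param values trials x features numeric matrix.
#' @param descriptors data.frame describing each feature column.
#' @param backend backend identifier (`"ica"` or `"st_pca"`).
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, backend) {
  stopifnot(nrow(descriptors) == ncol(values))
  structure(list(values = values, descriptors = descriptors,
                 backend = backend),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (backend: %s)\n",
              nrow(x$values), ncol(x$values), x$backend))
  invisible(x)
}

check_compatible <- function(epochs, model) {
  if (!identical(epochs$channels, model$channels)) {
    stop("channel set does not match the fitted model")
  }
  if (!isTRUE(all.equal(epochs$fs, model$fs))) {
    stop(sprintf("sampling rate mismatch: model fitted at %g Hz, data at %g Hz",
                 model$fs, epochs$fs))
  }
  invisible(TRUE)
}
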